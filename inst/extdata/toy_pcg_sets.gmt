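TERM_01	synthetic term 1	PCG1491	PCG1439	PCG0476	PCG1639	PCG0706	PCG1807	PCG0218	PCG0630	PCG1416	PCG1016	PCG0835	PCG1496	PCG0168	PCG1046	PCG1455	PCG1928	PCG0571	PCG1114	PCG0268	PCG0947	PCG0916	PCG1832	PCG1311	PCG0207	PCG0134	PCG1424	PCG0150	PCG1211	PCG1557	PCG0900	PCG1931	PCG1894	PCG0282	PCG0215	PCG1922	PCG0612	PCG1702	PCG1272	PCG1195	PCG0456	PCG0636	PCG1915	PCG0462	PCG1316	PCG0249	PCG1539	PCG1901	PCG0693	PCG0088	PCG1577	PCG0181	PCG0278	PCG0776	PCG0429	PCG1065	PCG1567
TERM_02	synthetic term 2	PCG0288	PCG0908	PCG0405	PCG0840	PCG0186	PCG0856	PCG1610	PCG1198	PCG0378	PCG0488	PCG1851	PCG1776	PCG0626	PCG0343	PCG0389	PCG0032	PCG1958	PCG1731	PCG0885	PCG0233	PCG1536	PCG1488	PCG0830	PCG1079	PCG0072	PCG0796	PCG0272	PCG0690	PCG0018	PCG0552	PCG0349	PCG1702	PCG0266	PCG0621	PCG0576	PCG0734	PCG0760	PCG1959	PCG1401	PCG1145	PCG1848	PCG0790	PCG1196	PCG0006	PCG1220	PCG0752	PCG1009	PCG1067
TERM_03	synthetic term 3	PCG1388	PCG1783	PCG1148	PCG0274	PCG0225	PCG0529	PCG1825	PCG1324	PCG0288	PCG0048	PCG0162	PCG1257	PCG0570	PCG0625	PCG0264	PCG0009	PCG0955	PCG1481	PCG1878	PCG1908	PCG0334	PCG0043	PCG0088	PCG1396	PCG1853	PCG0540	PCG1590
TERM_04	synthetic term 4	PCG0872	PCG1433	PCG0018	PCG1251	PCG1998	PCG0365	PCG1183	PCG1266	PCG1941	PCG1963	PCG1879	PCG0994	PCG0479	PCG1140	PCG0418	PCG1362	PCG1544	PCG1957	PCG0593	PCG0149	PCG0112	PCG0457	PCG0764	PCG1615	PCG0214	PCG1835	PCG1736	PCG1099	PCG0173	PCG0223	PCG1370	PCG0844	PCG0350	PCG1792	PCG0381	PCG1954	PCG0180	PCG0641
TERM_05	synthetic term 5	PCG0612	PCG1162	PCG0871	PCG1375	PCG1165	PCG1319	PCG0732	PCG0122	PCG1747	PCG1604	PCG0906	PCG1190	PCG1914	PCG0172	PCG0654	PCG0698	PCG1981	PCG0186	PCG0299	PCG1480	PCG1729	PCG1067	PCG1802	PCG0850	PCG1516	PCG1443	PCG1752
TERM_06	synthetic term 6	PCG0207	PCG1701	PCG1202	PCG0279	PCG1084	PCG0578	PCG1473	PCG1803	PCG1351	PCG1026	PCG1429	PCG1537	PCG0710	PCG0526	PCG1960	PCG0079	PCG1952	PCG0879	PCG0770	PCG1399	PCG1276	PCG1615	PCG1355	PCG1692	PCG1846	PCG1885	PCG0388	PCG0281	PCG0419	PCG0290	PCG1112	PCG1525	PCG1379	PCG1119	PCG1081	PCG0412	PCG0606	PCG0872	PCG1709	PCG0565	PCG1298	PCG0144	PCG1254	PCG1736	PCG1984	PCG0687
TERM_07	synthetic term 7	PCG1481	PCG1225	PCG0807	PCG1837	PCG0452	PCG0377	PCG1352	PCG1027	PCG1336	PCG0502	PCG1685	PCG0825	PCG0270	PCG0957	PCG0620	PCG1582	PCG0220	PCG0709	PCG0205	PCG1277	PCG1283	PCG1171	PCG1899	PCG1871	PCG0177
TERM_08	synthetic term 8	PCG0149	PCG1983	PCG0343	PCG0542	PCG1181	PCG0729	PCG1875	PCG1133	PCG1595	PCG1311	PCG1567	PCG1707	PCG1894	PCG0759	PCG0490	PCG0091	PCG1659	PCG1639	PCG1040	PCG1606	PCG0770	PCG0398	PCG0061	PCG0935	PCG1373	PCG1763	PCG0666	PCG1885	PCG0411	PCG0791	PCG0178	PCG0439	PCG1386	PCG1365	PCG0498	PCG0492	PCG1029	PCG0100	PCG0286
TERM_09	synthetic term 9	PCG0910	PCG0040	PCG0052	PCG1819	PCG0753	PCG0632	PCG0064	PCG1911	PCG0375	PCG0238	PCG0282	PCG1269	PCG0802	PCG0478	PCG0899	PCG1091	PCG1372	PCG0067	PCG1786	PCG1924	PCG1622	PCG1544	PCG1120	PCG1359	PCG1394	PCG1640	PCG1838	PCG0160	PCG1184	PCG0994	PCG1724	PCG1855	PCG0752	PCG0721	PCG0701	PCG1169	PCG0643	PCG1472	PCG0206	PCG0465	PCG1686	PCG1430
TERM_10	synthetic term 10	PCG0453	PCG0774	PCG1166	PCG0992	PCG0014	PCG0760	PCG0792	PCG1429	PCG1738	PCG0948	PCG0574	PCG0086	PCG0636	PCG0568	PCG1354	PCG1986	PCG1409	PCG1827	PCG0638	PCG1717	PCG1609	PCG0335	PCG1397	PCG1025	PCG0473	PCG0315	PCG0859	PCG1187	PCG1701	PCG0999	PCG1387	PCG0906	PCG1686	PCG0931	PCG1205	PCG0911
TERM_11	synthetic term 11	PCG0425	PCG0406	PCG1491	PCG1394	PCG0921	PCG0189	PCG1143	PCG0095	PCG1034	PCG1790	PCG1244	PCG1694	PCG1904	PCG0519	PCG0863	PCG0778	PCG0947	PCG1658	PCG1601	PCG1033	PCG0317	PCG1051	PCG1566	PCG0551	PCG0804	PCG1137	PCG0918	PCG1670	PCG1764	PCG0453	PCG1084	PCG1173	PCG1636	PCG1650	PCG0830	PCG1753	PCG0670	PCG0016	PCG0367	PCG1897	PCG0386	PCG1440	PCG0468	PCG1468	PCG1918	PCG0381	PCG1338
TERM_12	synthetic term 12	PCG0441	PCG1953	PCG1240	PCG0513	PCG0412	PCG1616	PCG1524	PCG0642	PCG1001	PCG1290	PCG0604	PCG1969	PCG1620	PCG1929	PCG0602	PCG1905	PCG0113	PCG1512	PCG0780	PCG0164	PCG0416	PCG0973	PCG1372	PCG1706	PCG0026	PCG0787	PCG0162	PCG1123	PCG0565	PCG0315	PCG0476	PCG0097	PCG1487	PCG1813	PCG0725	PCG1323	PCG0414	PCG0442	PCG1982	PCG1526	PCG1861	PCG0482	PCG1514	PCG1884	PCG1551	PCG0003	PCG1437	PCG0304	PCG1226	PCG1924	PCG0034	PCG1853	PCG1399
TERM_13	synthetic term 13	PCG0886	PCG0537	PCG0146	PCG1613	PCG1684	PCG1213	PCG1109	PCG1101	PCG0799	PCG1790	PCG0234	PCG0078	PCG0525	PCG1636	PCG1227
TERM_14	synthetic term 14	PCG0300	PCG0883	PCG1951	PCG1741	PCG0007	PCG1597	PCG0861	PCG0633	PCG1204	PCG1371	PCG1451	PCG1007	PCG0388	PCG1289	PCG0426	PCG0903	PCG0287	PCG0737	PCG1450	PCG0497	PCG1429	PCG1815	PCG1299	PCG1593	PCG1378	PCG1519	PCG1405	PCG1884	PCG1059	PCG0952	PCG0350	PCG1917	PCG0750	PCG1438	PCG0886	PCG0068	PCG0761	PCG0776	PCG1580	PCG1160	PCG1750	PCG1964	PCG1061	PCG0478	PCG0885	PCG1799	PCG0870	PCG1487	PCG0662	PCG0976	PCG0595	PCG0528	PCG1449	PCG0839	PCG1929	PCG1074	PCG0380
TERM_15	synthetic term 15	PCG1038	PCG0339	PCG1897	PCG1693	PCG1780	PCG1863	PCG1273	PCG1402	PCG0098	PCG1620	PCG1652	PCG0580	PCG1740	PCG1508	PCG1054	PCG1465	PCG0497	PCG1354	PCG1572	PCG1616	PCG1324	PCG0239	PCG0748	PCG1742	PCG0410	PCG0387	PCG0522	PCG1837	PCG0021	PCG1528	PCG1537	PCG1113	PCG0892	PCG0583	PCG1896	PCG0833
TERM_16	synthetic term 16	PCG0362	PCG0766	PCG1274	PCG0677	PCG0242	PCG0966	PCG1876	PCG1713	PCG1304	PCG1020	PCG1924	PCG1771	PCG0938	PCG0794	PCG1954	PCG1920	PCG1675	PCG1490	PCG0709	PCG0702	PCG0297	PCG0856	PCG1074	PCG0817	PCG0701	PCG1163	PCG1681	PCG0986	PCG0107	PCG1041	PCG1737	PCG0190	PCG0882	PCG0959	PCG0904	PCG1641	PCG0800	PCG0645	PCG0141	PCG1297	PCG1273	PCG1426	PCG0481	PCG0909	PCG1862	PCG1249	PCG0048	PCG1089	PCG1501	PCG0381	PCG0706	PCG1095	PCG0672	PCG1568	PCG0195	PCG0061	PCG1445	PCG0246	PCG1406
TERM_17	synthetic term 17	PCG0440	PCG0353	PCG1683	PCG1102	PCG0380	PCG1542	PCG0452	PCG1975	PCG1762	PCG0940	PCG0652	PCG1294	PCG0509	PCG1168	PCG0004	PCG0688	PCG1137	PCG0569	PCG0992	PCG1642	PCG1600	PCG0736	PCG1335	PCG1758	PCG1547	PCG0865	PCG1376	PCG1648	PCG0914	PCG0258	PCG0533	PCG0973	PCG1745	PCG1020	PCG1774	PCG0273	PCG1833	PCG0731	PCG0551	PCG1877	PCG0751	PCG1053	PCG0162	PCG1347	PCG1381	PCG1284	PCG1077
TERM_18	synthetic term 18	PCG0514	PCG1581	PCG0686	PCG0698	PCG0459	PCG1061	PCG1204	PCG1115	PCG1668	PCG0486	PCG1751	PCG1994	PCG1995	PCG0981	PCG0980	PCG0139	PCG0753	PCG0430	PCG0366	PCG0479	PCG0897	PCG0975	PCG0553	PCG1933	PCG0846	PCG1888	PCG1409	PCG0473	PCG1153	PCG0330
TERM_19	synthetic term 19	PCG0006	PCG0173	PCG1593	PCG1308	PCG0794	PCG1048	PCG0982	PCG1089	PCG0744	PCG1344	PCG1192	PCG0350	PCG0478	PCG0767	PCG0197	PCG0102	PCG1119	PCG0703	PCG1247	PCG0309	PCG1237	PCG1426	PCG1768	PCG1233	PCG1609	PCG0053	PCG0500	PCG1853	PCG1526	PCG0508	PCG0727	PCG0115	PCG1530	PCG0705	PCG1378
TERM_20	synthetic term 20	PCG0173	PCG0418	PCG0085	PCG1173	PCG0905	PCG0431	PCG1884	PCG0291	PCG0714	PCG0492	PCG0267	PCG1631	PCG1540	PCG1604	PCG0546	PCG0075	PCG1872	PCG1945	PCG0187	PCG1258	PCG0058	PCG0256	PCG0303	PCG0761	PCG0490	PCG1316	PCG1372	PCG1606	PCG0882	PCG0947	PCG1044	PCG0179	PCG1484	PCG0163	PCG1091	PCG1400	PCG0946	PCG0715	PCG1343	PCG0671	PCG0378	PCG1435	PCG0646	PCG0975	PCG1283	PCG1865	PCG0041	PCG1742	PCG1645
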