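activated_CD8_T_cell	synthetic immune-cell signature	gene1788	gene0131	gene0398	gene0377	gene1419	gene1230	gene1999	gene0844	gene1960	gene1076	gene1231	gene0845	gene1104	gene0863	gene0249
central_memory_CD8_T_cell	synthetic immune-cell signature	gene1502	gene1842	gene0390	gene0406	gene1656	gene0152	gene0296	gene0348	gene0900	gene1187	gene1040	gene0111	gene0999	gene0904	gene0831
effector_memory_CD8_T_cell	synthetic immune-cell signature	gene0562	gene1917	gene0759	gene1490	gene0010	gene0621	gene1823	gene1750	gene0489	gene0326	gene1248	gene1425	gene1469	gene1763	gene0591
activated_CD4_T_cell	synthetic immune-cell signature	gene1342	gene0439	gene1093	gene0255	gene0448	gene1145	gene0017	gene1177	gene0445	gene0339	gene1618	gene0133	gene0592	gene0928	gene1856
central_memory_CD4_T_cell	synthetic immune-cell signature	gene1678	gene1283	gene0987	gene1999	gene1177	gene0881	gene0775	gene1412	gene1083	gene1074	gene0990	gene1028	gene1898	gene0254	gene0192
effector_memory_CD4_T_cell	synthetic immune-cell signature	gene1980	gene0750	gene0805	gene0300	gene0283	gene1229	gene0637	gene1891	gene1508	gene0723	gene1599	gene1938	gene1283	gene0817	gene0542
T_follicular_helper_cell	synthetic immune-cell signature	gene0390	gene0616	gene1406	gene0822	gene0600	gene0218	gene0461	gene0102	gene1162	gene1782	gene0071	gene1608	gene1606	gene1275	gene0525
gamma_delta_T_cell	synthetic immune-cell signature	gene0353	gene1027	gene0889	gene0573	gene1914	gene1522	gene0397	gene1550	gene0060	gene0017	gene0112	gene1701	gene1789	gene0198	gene0888
type_1_helper_T_cell	synthetic immune-cell signature	gene0111	gene0614	gene0254	gene0759	gene1327	gene0289	gene0521	gene1274	gene0229	gene1776	gene1218	gene0620	gene0919	gene1405	gene1668
type_17_helper_T_cell	synthetic immune-cell signature	gene0457	gene0134	gene0944	gene0770	gene1349	gene0546	gene1010	gene1699	gene1233	gene0855	gene1429	gene0153	gene1321	gene0304	gene0588
type_2_helper_T_cell	synthetic immune-cell signature	gene0246	gene1981	gene0312	gene1360	gene1058	gene0657	gene0282	gene0817	gene0152	gene1708	gene0949	gene1451	gene1942	gene0009	gene1492
regulatory_T_cell	synthetic immune-cell signature	gene1745	gene1461	gene0248	gene0821	gene0245	gene0905	gene1985	gene1799	gene0613	gene1093	gene1919	gene0552	gene1000	gene1601	gene0524
activated_B_cell	synthetic immune-cell signature	gene1209	gene1306	gene1696	gene0836	gene1951	gene1927	gene1965	gene0835	gene0499	gene0667	gene0293	gene1559	gene1085	gene0141	gene1435
immature_B_cell	synthetic immune-cell signature	gene1778	gene1461	gene0125	gene0708	gene1359	gene0897	gene0136	gene0756	gene1805	gene0945	gene0419	gene1106	gene1488	gene0054	gene1391
memory_B_cell	synthetic immune-cell signature	gene1730	gene0720	gene0929	gene0890	gene0002	gene0579	gene1084	gene0730	gene1173	gene1423	gene0271	gene0356	gene1840	gene1456	gene0719
natural_killer_cell	synthetic immune-cell signature	gene1848	gene1574	gene0199	gene1478	gene1811	gene0116	gene0194	gene1657	gene0492	gene1469	gene0723	gene0554	gene0370	gene1337	gene0297
CD56bright_natural_killer_cell	synthetic immune-cell signature	gene1696	gene0995	gene0761	gene1216	gene0692	gene0953	gene0846	gene1852	gene0020	gene0790	gene1560	gene1316	gene0626	gene1676	gene1797
CD56dim_natural_killer_cell	synthetic immune-cell signature	gene1130	gene0262	gene0598	gene0201	gene1805	gene1860	gene0918	gene1295	gene0291	gene0623	gene0219	gene0610	gene1433	gene1812	gene0500
myeloid_derived_suppressor_cell	synthetic immune-cell signature	gene0250	gene1923	gene1488	gene0607	gene0067	gene1696	gene1076	gene0246	gene1965	gene0876	gene0093	gene0091	gene1572	gene0540	gene1804
natural_killer_T_cell	synthetic immune-cell signature	gene1051	gene1459	gene1330	gene1081	gene0218	gene0731	gene1527	gene0868	gene1440	gene1887	gene0073	gene1691	gene1104	gene1510	gene1549
activated_dendritic_cell	synthetic immune-cell signature	gene0897	gene1033	gene0847	gene1806	gene0136	gene0735	gene1737	gene0773	gene1923	gene1297	gene1804	gene1376	gene0446	gene1137	gene0097
plasmacytoid_dendritic_cell	synthetic immune-cell signature	gene1152	gene0887	gene1997	gene0981	gene0310	gene1975	gene1513	gene0124	gene0075	gene0957	gene0580	gene0439	gene1857	gene0101	gene0152
immature_dendritic_cell	synthetic immune-cell signature	gene1846	gene1715	gene1772	gene0610	gene1156	gene1587	gene0756	gene1391	gene0496	gene1777	gene1299	gene1915	gene0846	gene0853	gene1992
macrophage	synthetic immune-cell signature	gene1529	gene0540	gene1966	gene0278	gene0621	gene0266	gene0717	gene0558	gene1067	gene1259	gene1772	gene0453	gene1465	gene1289	gene1170
eosinophil	synthetic immune-cell signature	gene1161	gene0553	gene0356	gene1415	gene0628	gene1832	gene1362	gene0164	gene1855	gene1528	gene0697	gene1006	gene0265	gene1390	gene1977
mast_cell	synthetic immune-cell signature	gene0343	gene1367	gene1818	gene0296	gene0820	gene1830	gene1700	gene1910	gene0936	gene1617	gene1002	gene0511	gene0183	gene1234	gene0854
monocyte	synthetic immune-cell signature	gene1094	gene0592	gene1143	gene0436	gene1557	gene0501	gene0526	gene1556	gene0198	gene1145	gene1385	gene0445	gene0336	gene0763	gene1623
neutrophil	synthetic immune-cell signature	gene1073	gene0381	gene0869	gene0071	gene0856	gene0040	gene1162	gene1996	gene1071	gene1110	gene0459	gene1408	gene1203	gene1605	gene1906
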