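stromal_signature	synthetic stand-in for the published stromal signature	gene0347	gene1005	gene0025	gene1774	gene0063	gene0487	gene1505	gene1735	gene0044	gene1622	gene1076	gene0435	gene0708	gene0300	gene1430	gene0748	gene1390	gene1799	gene0293	gene0459	gene1006	gene1527	gene0615	gene1698	gene0199	gene0413	gene1619	gene0517	gene0381	gene1222	gene1966	gene1604	gene1469	gene1805	gene0897	gene0630	gene1894	gene0746	gene0919	gene1945	gene1702	gene1061	gene1627	gene1093	gene0323	gene1617	gene0023	gene1861	gene0640	gene1968
immune_signature	synthetic stand-in for the published immune signature	gene1316	gene0350	gene0276	gene0177	gene0897	gene1649	gene1367	gene0131	gene0084	gene1296	gene1945	gene1932	gene0818	gene1337	gene0777	gene0199	gene1579	gene1444	gene0174	gene1229	gene1007	gene1811	gene1732	gene1546	gene0530	gene0657	gene1728	gene1526	gene0090	gene0598	gene0766	gene1597	gene1412	gene1390	gene0812	gene1841	gene0947	gene1079	gene0680	gene1329	gene0511	gene1210	gene0241	gene1906	gene1832	gene0196	gene1882	gene0056	gene1058	gene0162
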