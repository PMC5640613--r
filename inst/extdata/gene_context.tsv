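gene	N_a	N_s	length	ncmr
G0001	4738.5	1579.5	2106	1.2508620094545612e-6
G0002	1534.5	511.5	682	3.1681010635364055e-7
G0003	2184.75	728.25	971	9.611912985160258e-7
G0004	4299.75	1433.25	1911	7.698710788671675e-7
G0005	3075.75	1025.25	1367	8.115657535893095e-7
G0006	7310.25	2436.75	3249	1.1646713011117688e-6
G0007	2486.25	828.75	1105	9.844353730692184e-7
G0008	2837.25	945.75	1261	1.0539682485359535e-6
G0009	1489.5	496.5	662	3.4255466233770397e-6
G0010	3408.75	1136.25	1515	7.261530981924695e-7
G0011	5271.75	1757.25	2343	1.8325246308518352e-6
G0012	2182.5	727.5	970	1.4270104051731266e-6
G0013	5267.25	1755.75	2341	9.036538421786634e-7
G0014	2841.75	947.25	1263	2.02510202754674e-6
G0015	1131.75	377.25	503	1.9048507686968435e-6
G0016	5240.25	1746.75	2329	1.3400894909798686e-6
G0017	4846.5	1615.5	2154	1.8955146396097385e-6
G0018	3766.5	1255.5	1674	6.460049949793364e-7
G0019	5008.5	1669.5	2226	9.330454468145481e-7
G0020	3008.25	1002.75	1337	5.501305491119161e-7
G0021	2241	747	996	1.179045292089608e-6
G0022	4333.5	1444.5	1926	5.820395854097801e-7
G0023	3654	1218	1624	7.720853607983037e-7
G0024	4428	1476	1968	9.61677297366838e-7
G0025	3120.75	1040.25	1387	8.397665001530255e-7
G0026	4203	1401	1868	3.233072825649969e-7
G0027	7101	2367	3156	8.665232008745574e-7
G0028	3478.5	1159.5	1546	1.150619457346985e-6
G0029	2207.25	735.75	981	4.592940880589475e-7
G0030	10872	3624	4832	1.3127049639830004e-6
G0031	3177	1059	1412	4.6335865067990955e-7
G0032	1273.5	424.5	566	8.639590003176572e-7
G0033	4419	1473	1964	9.459193407010337e-7
G0034	7870.5	2623.5	3498	1.1380088154716274e-6
G0035	2272.5	757.5	1010	1.2147211395092135e-6
G0036	1971	657	876	2.739487442182738e-6
G0037	2490.75	830.25	1107	8.505819737710666e-7
G0038	4920.75	1640.25	2187	1.2084409195521916e-6
G0039	4234.5	1411.5	1882	4.502475712399716e-7
G0040	3172.5	1057.5	1410	1.3986910878587436e-6
G0041	2304	768	1024	1.2372135750126079e-6
G0042	3782.25	1260.75	1681	1.411705135605444e-6
G0043	5906.25	1968.75	2625	6.09351761731975e-7
G0044	3649.5	1216.5	1622	1.5232826925372412e-6
G0045	2391.75	797.25	1063	2.336880766269919e-6
G0046	4232.25	1410.75	1881	2.2104587979014622e-06
G0047	1980	660	880	6.816786021840965e-7
G0048	4126.5	1375.5	1834	8.685219754917437e-7
G0049	3267	1089	1452	1.0030098936556808e-6
G0050	3951	1317	1756	7.535316595817886e-7
G0051	2493	831	1108	1.3399813048843105e-6
G0052	2144.25	714.75	953	1.0547237448046159e-6
G0053	10455.75	3485.25	4647	5.198710428114596e-7
G0054	2495.25	831.75	1109	9.523420924337884e-7
G0055	1764	588	784	4.919671278333213e-7
G0056	4347	1449	1932	8.812126037401273e-7
G0057	2202.75	734.25	979	1.0156951681440885e-6
G0058	1588.5	529.5	706	9.826385157619396e-7
G0059	6156	2052	2736	1.2942195173553909e-6
G0060	2018.25	672.75	897	1.1808000351212936e-6
G0061	5395.5	1798.5	2398	1.6024901369082884e-6
G0062	2571.75	857.25	1143	1.1686201959347864e-6
G0063	4362.75	1454.25	1939	5.800142771359544e-7
G0064	2830.5	943.5	1258	1.7010737952329178e-6
G0065	6552	2184	2912	6.093684773361891e-7
G0066	1908	636	848	1.7767403710822048e-6
G0067	6840	2280	3040	1.5541976016740245e-6
G0068	2497.5	832.5	1110	1.7878249310268454e-6
G0069	2706.75	902.25	1203	9.52410834809376e-7
G0070	3811.5	1270.5	1694	9.544538256515395e-7
G0071	4549.5	1516.5	2022	1.3976626961917384e-6
G0072	3179.25	1059.75	1413	6.960232345955839e-7
G0073	1199.25	399.75	533	3.1207091983611805e-6
G0074	4522.5	1507.5	2010	8.755424931233205e-7
G0075	4311	1437	1916	8.243585455686633e-7
G0076	2040.75	680.25	907	9.273742689236009e-7
G0077	6367.5	2122.5	2830	7.732738633971741e-7
G0078	5919.75	1973.25	2631	1.1872309147094995e-6
G0079	5143.5	1714.5	2286	9.84999534109173e-7
G0080	7589.25	2529.75	3373	7.796485216261969e-7
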