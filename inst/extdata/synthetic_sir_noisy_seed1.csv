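# synthetic SIR epidemic dataset (reference protocol)
# RK4, beta: 0.5, sigma: 1/14 (0.0714285714...), S0: 999, I0: 1, R0: 0
# 60 daily observations; 1% additive white noise (per-series sd scale)
# noise seed: 1 (dinnr::sir_synthetic_data(seed = 1))
# N: 1000
# noisy: true
t,S,I,R
0,996.5013290255410539,5.46553177599387,-1.860681353775764
1,999.1094064801717423,1.46098290377617,5.028213086938823
2,994.0891233927853818,3.63456548640045,-0.563308057909383
3,1002.3231718581392897,3.65647592896962,-0.224978077769331
4,995.0394629281789776,4.13648084825511,0.387842567630859
5,987.0427790872955711,8.78839462772588,3.868209607529140
6,987.0740649424047888,9.51664861174197,1.726794656046343
7,980.2282904875328313,22.30187367080199,3.001343789087184
8,967.7949957170288826,29.91357860609222,2.366104529836151
9,946.7768332542135568,48.55820264020825,6.294096080215375
10,928.4543381598502947,67.06674670232199,11.614196964820540
11,887.5112176938710036,95.56793908598328,14.990020613908802
12,833.2070914716142624,139.94942489277594,27.455782667891341
13,760.6934369013479227,191.45224286641061,31.699968148010647
14,692.0362471122751913,256.74337973389493,54.503661111602085
15,592.9744482512696777,332.91436923152838,68.823507820943760
16,493.0273587316449380,405.21584255872796,99.761118823328189
17,399.4869989109943731,471.98557265214816,130.351291619655001
18,311.5848530669616707,523.87589745049399,165.554890018778764
19,237.4395585736037049,557.13343545980990,206.490451418554784
20,180.5918532053364345,574.72096339729467,240.255095533770202
21,135.6151939833255256,578.64282699392550,292.937193552405517
22,99.6548028658479410,573.10189349165614,323.608219255487256
23,67.0272432876040511,552.22223088240855,368.278255198808495
24,59.5582672837095828,535.11579012759091,404.798705022999115
25,43.7464019864994498,510.45219007490175,443.435445287426205
26,33.6742444658431594,485.98370489841471,489.373006093635411
27,21.2361548713534916,457.00553560038617,515.390451080578828
28,19.7956615145707033,431.91792207128231,542.336848413748498
29,19.2741687245362385,405.94514497769916,570.910924921591345
30,19.8860130679632903,379.51539445083807,606.664645687022357
31,11.6225386465233136,358.88363305115934,631.261486142393437
32,11.6714992851314889,336.04790078673352,654.814789568147944
33,8.4005818788011482,313.63015798657955,675.638849108041541
34,1.9150520471319394,294.91165348161792,695.161092514394795
35,4.7772964292104607,273.81243641448799,716.839394753234728
36,4.0653948282699508,252.36189790671321,743.304018752572006
37,4.7485057591893405,236.73837243781773,754.925887344560692
38,8.8315750471736347,219.65532287563624,768.532340269125598
39,7.0362288023051462,206.18829101693717,795.813646148743032
40,2.9560337335290900,192.00665229907773,804.790921216209881
41,2.2799417115416691,180.23276961982927,815.677405517809575
42,5.7962178110951044,166.30573640000395,832.876816042751329
43,5.0015708674113668,156.93855490801221,843.833874197940531
44,-0.1685202197276969,144.82432621372342,849.102607010767429
45,-0.4188413114973031,139.42913958090790,869.566898006393785
46,3.7043540238457617,128.23781910549374,869.906758578974859
47,5.1818150406029861,119.97802972719185,874.359243327173999
48,1.5508620589789570,110.95902914889422,887.225317583535457
49,5.4097340284525615,105.87245974861395,896.123233086329606
50,3.3915128130907974,94.56809896128203,910.933887377891665
51,-0.7189725230468655,88.36963238365794,909.438932036940855
52,3.0101334737349577,85.81007049143783,916.884182210242102
53,-2.9199285885421622,76.26769192947793,920.654035510680046
54,7.2422220736508987,71.80700704462633,925.052619291907490
55,9.3732028011868440,66.53589627819439,931.131827774076328
56,-0.0376103272442521,62.07956817124084,938.794934372731177
57,-2.7800728854595342,57.87599173355600,947.852278197443638
58,3.6184553690745873,55.32539072567698,948.025703440678626
59,0.7725040299597423,50.35980183954000,952.441427834913725
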