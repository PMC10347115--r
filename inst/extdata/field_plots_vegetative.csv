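plot_id,genotype_id,fresh_g,dry_g,water_pct,spad,height_cm,stage
1,G01,940,260,72.3,40.48,84,vegetative
2,G02,1000,280,72.0,37.72,105.2,vegetative
3,G03,1020,280,72.5,36.42,96.2,vegetative
4,IRBB 66,700,240,65.7,41.68,87,vegetative
5,G05,1380,360,73.9,40.74,117.2,vegetative
6,G06,1380,380,72.5,41.24,145.8,vegetative
7,G07,1140,320,71.9,39.58,111,vegetative
8,G08,860,240,72.1,38.66,96.8,vegetative
9,G09,880,260,70.5,40.2,106,vegetative
10,G10,840,280,66.7,40.02,109.4,vegetative
11,G11,1180,320,72.9,42.26,104.4,vegetative
12,G12,840,260,69.0,35.06,122,vegetative
13,IR 64-21,940,300,68.1,41,99.4,vegetative
14,G14,1060,280,73.6,38.64,90.8,vegetative
15,G15,700,220,68.6,34.86,104.6,vegetative
16,G16,820,260,68.3,36.4,95.8,vegetative
17,G17,980,300,69.4,36.04,98.2,vegetative
18,G18,1260,400,68.3,43.48,113.6,vegetative
19,G19,1120,320,71.4,38.62,98.8,vegetative
20,G20,1260,360,71.4,44.76,116,vegetative
21,G21,1200,340,71.7,40.94,117.2,vegetative
22,G22,1160,320,72.4,38.14,97.2,vegetative
23,G23,840,260,69.0,33.5,95.8,vegetative
24,IRBB 66,780,280,64.1,41.2,90,vegetative
25,G25,1060,340,67.9,42.36,115.2,vegetative
26,G26,740,240,67.6,41.14,96.8,vegetative
27,G27,780,280,64.1,35.14,129.6,vegetative
28,G28,600,200,66.7,39.28,104.4,vegetative
29,G29,860,280,67.4,38.02,100.8,vegetative
30,G30,840,280,66.7,37,122.6,vegetative
31,IR 64-21,900,280,68.9,38.02,106.6,vegetative
32,G32,1180,340,71.2,38.44,116.2,vegetative
33,G33,980,380,61.2,41.9,113.8,vegetative
34,G34,1440,300,79.2,37.32,118.8,vegetative
35,G35,1180,320,72.9,37,131.4,vegetative
36,Fedearroz 67,1000,280,72.0,35.66,111.8,vegetative
37,G37,760,260,65.8,34.64,94.4,vegetative
38,G38,980,300,69.4,32.7,109.2,vegetative
39,G39,1040,340,67.3,35.16,131.4,vegetative
40,G40,700,240,65.7,37.36,100,vegetative
41,G41,760,240,68.4,41.32,99.2,vegetative
42,G42,960,280,70.8,37.94,93.6,vegetative
43,G43,760,260,65.8,39.28,106,vegetative
44,Fedearroz 67,660,220,66.7,32.64,97.6,vegetative
45,G45,940,320,66.0,33.3,106.8,vegetative
46,G46,1000,340,66.0,34.42,152.4,vegetative
47,G47,980,280,71.4,37.84,108,vegetative
48,G48,1240,360,71.0,37.52,109.2,vegetative
49,G49,1220,360,70.5,34.9,121.4,vegetative
50,G50,760,260,65.8,35.64,108,vegetative
51,G51,1060,300,71.7,36.1,118,vegetative
52,G52,1200,380,68.3,38.14,131,vegetative
53,G53,920,300,67.4,37.42,119.6,vegetative
54,G54,1320,360,72.7,37.58,133.6,vegetative
55,G55,900,280,68.9,40.08,112,vegetative
56,G56,1180,340,71.2,38.72,129.2,vegetative
57,G57,940,300,68.1,34.04,103.4,vegetative
58,G58,780,240,69.2,30.58,88,vegetative
59,G59,1080,280,74.1,39.88,91,vegetative
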