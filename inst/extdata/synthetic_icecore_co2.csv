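"age_ka","co2_ppm"
20.95,193.8
20.8,196
20.65,195.5
20.5,195.6
20.35,197.8
20.2,196.7
20.05,198.3
19.9,196.9
19.75,197.9
19.6,198.4
19.45,199.8
19.3,200.7
19.15,200.9
19,200.5
18.85,202.1
18.7,201.6
18.55,201.9
18.4,204.9
18.25,204.5
18.1,203.8
17.95,207.1
17.8,204.9
17.65,207
17.5,209.1
17.35,207.5
17.2,210.2
17.05,210.4
16.9,214
16.75,210.7
16.6,213.8
16.45,216.4
16.3,215.2
16.15,217.5
16,218.2
15.85,220.2
15.7,218.1
15.55,224.9
15.4,219.9
15.25,223.3
15.1,224.1
14.95,226.8
14.8,230.2
14.65,228.4
14.5,229.2
14.35,231.4
14.2,233.1
14.05,235.2
13.9,236.9
13.75,238.8
13.6,238.8
13.45,242
13.3,240.6
13.15,241.7
13,243.6
12.85,247.5
12.7,246.2
12.55,246.3
12.4,249.9
12.25,248.8
12.1,251.6
11.95,253.4
11.8,253.8
11.65,254.3
11.5,256.7
11.35,255.1
11.2,259
11.05,259.4
10.9,259.2
10.75,258.9
10.6,260.4
10.45,261.9
10.3,263.7
10.15,264.7
10,265.8
9.85,263.4
9.7,267
9.55,266
9.4,268.7
9.25,265.9
9.1,269
8.95,269.2
8.8,268.8
8.65,270.8
8.5,268.9
8.35,272.8
8.2,271.8
8.05,274.7
7.9,273.3
7.75,273.9
7.6,273.7
7.45,273.1
7.3,275.3
7.15,273.6
7,272.5
6.85,272.7
6.7,276.3
6.55,274.6
6.4,277.9
6.25,276
6.1,276.4
5.95,277.5
5.8,279.7
5.65,278.4
5.5,277.3
5.35,277.8
5.2,278.5
5.05,278.9
4.9,277.4
4.75,277.7
4.6,278.8
4.45,276.6
4.3,277.8
4.15,278.7
4,276.1
3.85,278
3.7,279.9
3.55,280.1
3.4,280.4
3.25,278.5
3.1,278.1
2.95,279.5
2.8,279.1
2.65,282.3
2.5,278.6
2.35,281.2
2.2,279.5
2.05,280.7
1.9,280.7
1.75,277.2
1.6,279.7
1.45,281.5
1.3,279.5
1.15,278.8
1,278.5
0.85,280.8
0.7,280.4
0.55,280
0.4,279.9
0.25,280.8
0.1,281.2
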