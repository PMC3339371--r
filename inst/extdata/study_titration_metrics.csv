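patient,peep,e_lung,edrs_median,edrs_q1,edrs_q3,edrs_area
1,0,53.8,63.1,46.9,114.9,84.6
1,5,47.0,53.8,43.0,80.2,49.5
1,10,41.2,43.6,38.4,54.5,37.1
1,15,32.8,35.0,33.3,39.4,28.9
1,20,32.8,33.4,32.0,34.2,26.6
1,25,32.1,31.1,32.0,32.4,25.7
1,27,32.2,32.2,31.9,32.6,25.7
2,0,27.7,30.8,26.3,45.1,34.0
2,5,25.3,26.4,23.7,31.4,24.8
2,10,22.8,23.1,22.0,24.3,21.0
2,15,22.3,22.1,22.0,22.6,20.2
2,20,22.6,22.5,22.4,22.6,20.3
2,22,23.1,23.1,22.9,23.2,20.7
3,0,24.0,26.9,22.6,36.9,37.7
3,5,21.6,22.1,20.2,25.6,27.6
3,10,18.3,18.3,18.0,19.0,22.2
3,15,17.3,17.3,17.2,17.4,20.8
3,20,17.4,17.5,17.1,17.5,19.1
3,25,18.1,17.8,17.4,18.7,19.7
3,28,19.1,19.2,17.9,19.7,18.9
4,0,60.2,73.2,50.4,144.4,102.2
4,5,59.7,70.4,49.9,126.9,91.2
4,10,50.1,54.5,41.7,82.3,61.7
4,15,35.1,36.8,30.6,43.9,37.9
4,20,27.8,28.5,25.6,31.4,31.7
4,25,25.3,25.9,21.6,28.4,48.1
4,30,22.5,23.1,19.4,25.5,47.5
5,0,87.4,105.7,80.6,199.8,118.7
5,5,84.0,97.8,77.5,166.8,99.9
5,10,81.2,89.3,74.3,143.4,89.1
5,15,74.3,79.4,68.6,107.3,70.6
5,20,65.7,67.3,61.4,79.4,75.7
5,25,53.1,52.3,52.0,55.8,42.9
6,0,27.1,30.4,25.9,39.1,29.4
6,5,25.5,26.2,25.5,27.2,23.8
6,10,22.8,23.3,22.4,23.5,20.8
6,15,21.6,21.6,21.5,21.8,21.6
6,20,21.8,21.8,21.3,22.5,19.5
6,25,23.4,23.3,22.6,23.9,20.8
7,0,47.7,49.3,46.1,62.4,37.6
7,5,42.5,42.2,41.5,43.1,33.8
7,10,45.5,44.3,41.8,47.7,31.3
7,15,55.7,53.6,48.8,59.7,37.9
7,16,55.3,52.4,50.3,57.6,32.1
8,0,41.7,45.7,37.9,67.8,55.1
8,5,35.5,37.2,32.9,43.0,38.5
8,10,31.2,31.8,29.9,33.5,32.0
8,15,28.7,28.8,28.0,29.8,29.0
8,20,27.5,27.4,27.1,27.9,27.5
8,25,26.6,26.8,26.3,27.0,24.1
8,30,27.0,27.0,26.8,27.5,24.3
9,0,51.3,58.1,47.1,100.8,106.5
9,5,39.1,40.5,36.4,52.8,55.2
9,10,38.2,39.9,35.8,48.7,51.3
9,15,31.1,31.2,30.2,33.6,38.3
9,20,28.2,28.3,27.9,29.0,34.1
9,25,26.2,26.3,26.3,26.5,31.6
9,30,26.1,26.2,25.8,26.5,31.3
10,0,51.0,54.4,48.1,76.2,74.7
10,5,44.1,45.2,41.9,51.8,52.6
10,10,39.2,39.4,38.4,41.7,44.0
10,15,35.8,35.9,35.7,36.0,39.5
10,20,33.9,33.9,33.7,34.1,37.3
10,25,34.0,33.9,33.4,34.6,37.2
10,27,34.2,33.9,33.2,34.8,37.3
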