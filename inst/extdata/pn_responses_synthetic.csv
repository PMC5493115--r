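"class_id","glomerulus","O01","O02","O03","O04","O05","O06","O07","O08","O09","O10","O11","O12","O13","O14","O15","O16","O17"
"PN01","G01",72.6666666666667,40.6666666666667,90.3333333333333,91.3333333333333,28.3333333333333,6.66666666666667,43.3333333333333,89,4.66666666666667,7.66666666666667,6.66666666666667,1.33333333333333,9.33333333333333,4.33333333333333,2.33333333333333,7.33333333333333,3
"PN02","G02",4.66666666666667,9,-2.66666666666667,0.333333333333333,-3.66666666666667,1.66666666666667,4.33333333333333,-3,7.66666666666667,0.666666666666667,14.6666666666667,-1.33333333333333,59.6666666666667,11,88,3.66666666666667,66.3333333333333
"PN03","G03",0.333333333333333,-2.33333333333333,11,5.66666666666667,0,-0.666666666666667,2.33333333333333,5,5.33333333333333,2.33333333333333,3.66666666666667,48.6666666666667,3,22.3333333333333,10.6666666666667,19,1.66666666666667
"PN04","G04",49,50.6666666666667,1,78,29.6666666666667,54,9.33333333333333,78.3333333333333,0.333333333333333,5.33333333333333,7.66666666666667,10.6666666666667,2.66666666666667,0.333333333333333,0.333333333333333,3.33333333333333,8
"PN05","G05",11.6666666666667,7.33333333333333,11,4.66666666666667,9,6.33333333333333,2.66666666666667,2.33333333333333,76.6666666666667,4.66666666666667,49,3.66666666666667,56.6666666666667,8.66666666666667,95.6666666666667,2.66666666666667,79.3333333333333
"PN06","G06",4.66666666666667,1.33333333333333,5,3.66666666666667,-1.33333333333333,3.33333333333333,3,5.33333333333333,4.66666666666667,62,1.66666666666667,36.6666666666667,-2,96.6666666666667,3.33333333333333,95,0.333333333333333
"PN07","G07",7,87,6.66666666666667,2.33333333333333,2,54.3333333333333,91.6666666666667,63.3333333333333,2.66666666666667,11.6666666666667,3.33333333333333,3.33333333333333,0.666666666666667,-0.333333333333333,1.33333333333333,3.66666666666667,-1.66666666666667
"PN08","G08",2,6.66666666666667,5,6.66666666666667,1.66666666666667,3,3.33333333333333,3.33333333333333,9.33333333333333,4,21.3333333333333,0,76.6666666666667,0.666666666666667,59,-2.33333333333333,39.6666666666667
"PN09","G09",3,7.33333333333333,4,7.66666666666667,10.3333333333333,1.66666666666667,10,7.33333333333333,2.66666666666667,80,9.33333333333333,68.6666666666667,6.33333333333333,58.6666666666667,6.33333333333333,13.6666666666667,4.33333333333333
"PN10","G10",35.3333333333333,66,37.3333333333333,37,97.3333333333333,55.3333333333333,99.6666666666667,3,3.66666666666667,5.33333333333333,6.66666666666667,0,8,8.66666666666667,1,1,5.33333333333333
"PN11","G11",2.33333333333333,-2.66666666666667,-4,2,-2.33333333333333,-1.66666666666667,-2.33333333333333,-0.666666666666667,5,-3,77.6666666666667,6,3.66666666666667,-2.33333333333333,76,-2.66666666666667,77.3333333333333
"PN12","G12",4.33333333333333,4.66666666666667,-1.33333333333333,2.66666666666667,4.33333333333333,7.66666666666667,6,1.66666666666667,3.33333333333333,44,1.66666666666667,2,7,3,2,13.6666666666667,5.66666666666667
"PN13","G13",-4.33333333333333,35.6666666666667,90.6666666666667,59.6666666666667,68.3333333333333,101.333333333333,54.3333333333333,25,-1.33333333333333,3.33333333333333,3.66666666666667,1.33333333333333,-2,-3.33333333333333,-0.666666666666667,2.66666666666667,0.333333333333333
"PN14","G14",3.33333333333333,3.33333333333333,4,11.3333333333333,4.33333333333333,4,11,4,6,5,19.3333333333333,7.33333333333333,76.6666666666667,9,75.6666666666667,7.66666666666667,48
"PN15","G15",-2,1,-1,6,0,7.33333333333333,1.33333333333333,-1.66666666666667,4.33333333333333,57,1.66666666666667,69.3333333333333,-1,45.3333333333333,0.666666666666667,61.3333333333333,2
"PN16","G16",43.6666666666667,68.6666666666667,50.6666666666667,75.6666666666667,30,22.3333333333333,79,11,4,12.6666666666667,5.66666666666667,15,11.6666666666667,6.33333333333333,5,1.33333333333333,8
"PN17","G17",-1,1.33333333333333,7.66666666666667,6.33333333333333,9.33333333333333,10.3333333333333,1.66666666666667,0,2.33333333333333,4.33333333333333,48.6666666666667,1,53.3333333333333,-0.333333333333333,71,-2.66666666666667,29.6666666666667
"PN18","G18",4,3,4,6.33333333333333,8.66666666666667,2,3.66666666666667,9.66666666666667,4.66666666666667,31.6666666666667,8.66666666666667,34.3333333333333,11.3333333333333,81,6.33333333333333,13.6666666666667,7.66666666666667
"PN19","G19",30,67.6666666666667,21.6666666666667,26,21,48.6666666666667,73,24.6666666666667,8,4.33333333333333,6.33333333333333,6.66666666666667,-3.33333333333333,9.33333333333333,-1.33333333333333,5.33333333333333,4
"PN20","G20",10.3333333333333,2,7.33333333333333,13,0.333333333333333,2.33333333333333,5.66666666666667,3.66666666666667,83,3.66666666666667,3.33333333333333,6.33333333333333,52,2.66666666666667,34.6666666666667,7.33333333333333,27.3333333333333
"PN21","G21",-2,-1.33333333333333,0.666666666666667,4.66666666666667,4.33333333333333,-0.666666666666667,2.66666666666667,1.66666666666667,-1,69.6666666666667,-3.33333333333333,4,1.66666666666667,88.3333333333333,3,5.66666666666667,2
"PN22","G22",1,27,100.333333333333,26.3333333333333,76.3333333333333,87.3333333333333,-1.66666666666667,32.3333333333333,6.33333333333333,8,3.33333333333333,3,9.66666666666667,5.33333333333333,-2,1.66666666666667,2.33333333333333
"PN23","G23",8.33333333333333,5.66666666666667,6.66666666666667,10.3333333333333,6,5,7.66666666666667,2.33333333333333,26,5,35.3333333333333,2,76,4,63.3333333333333,7.66666666666667,20
"PN24","G24",-2.33333333333333,-0.666666666666667,-0.666666666666667,-0.666666666666667,0.666666666666667,7.66666666666667,2,7.33333333333333,-1.33333333333333,15,4,48,-0.666666666666667,0.666666666666667,3.66666666666667,0,-3.66666666666667
"PN25","G25",20.6666666666667,49,38.6666666666667,5,78.6666666666667,60.3333333333333,49.3333333333333,83,0.333333333333333,4,9,1,1.33333333333333,0.333333333333333,1.66666666666667,2,10.6666666666667
"PN26","G26",-1,1,1.66666666666667,1.33333333333333,-1,18,2.66666666666667,9.66666666666667,52.3333333333333,10.3333333333333,39.6666666666667,9,30.6666666666667,2.66666666666667,23.6666666666667,2.66666666666667,19
"PN27","G27",5.33333333333333,5.66666666666667,4.33333333333333,4.33333333333333,3.66666666666667,6,2.33333333333333,4,3.33333333333333,70,9,29.3333333333333,7.66666666666667,29.3333333333333,6,50,1.33333333333333
"PN28","G28",84.3333333333333,21.6666666666667,1,47,53,7,78.6666666666667,78.6666666666667,4.33333333333333,3.66666666666667,5.33333333333333,5.66666666666667,2.66666666666667,10,12.6666666666667,3.33333333333333,4.66666666666667
"PN29","G29",1.33333333333333,-0.666666666666667,7.66666666666667,7.33333333333333,1,1,2.33333333333333,3.33333333333333,14.3333333333333,4.33333333333333,70.6666666666667,6.66666666666667,37,13.3333333333333,54.3333333333333,10,68.6666666666667
"PN30","G30",6,1.66666666666667,0.666666666666667,3.33333333333333,3,5.33333333333333,6.66666666666667,7,7,77,3.33333333333333,88,0.333333333333333,20.6666666666667,2.66666666666667,83.3333333333333,0.666666666666667
"PN31","G31",32,13.3333333333333,82,62,35.3333333333333,4.33333333333333,58.6666666666667,49.6666666666667,5.66666666666667,6.33333333333333,2.66666666666667,1.66666666666667,0.666666666666667,-0.666666666666667,7,2.66666666666667,-3
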