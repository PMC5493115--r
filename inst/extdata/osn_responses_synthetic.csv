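"class_id","glomerulus","O01","O02","O03","O04","O05","O06","O07","O08","O09","O10","O11","O12","O13","O14","O15","O16","O17"
"OSN01","G01",88,47,86,99.6666666666667,25.6666666666667,4.66666666666667,38.3333333333333,95.6666666666667,6,6.33333333333333,6,5.66666666666667,8.66666666666667,5,4.66666666666667,4.33333333333333,5.66666666666667
"OSN02","G02",6,1,-0.333333333333333,13,1,-3,3.33333333333333,1.66666666666667,7.33333333333333,1,15.3333333333333,5.33333333333333,65.3333333333333,7.33333333333333,88.3333333333333,7.66666666666667,73.6666666666667
"OSN03","G03",0.666666666666667,6.66666666666667,9.33333333333333,15.3333333333333,1.66666666666667,-2,5,8,4,0,3.66666666666667,55,9.66666666666667,30,6.66666666666667,13.6666666666667,7
"OSN04","G04",56,54,0.666666666666667,77,33,55.3333333333333,13,67.6666666666667,0.333333333333333,1,7.33333333333333,2.66666666666667,2.66666666666667,2.66666666666667,1,7.66666666666667,5.33333333333333
"OSN06","G06",9,2,6.66666666666667,5,1,1.66666666666667,12.6666666666667,11.6666666666667,8.66666666666667,56.6666666666667,6,27.3333333333333,1.33333333333333,104.333333333333,-2.33333333333333,91.6666666666667,7
"OSN07","G07",1.66666666666667,74.3333333333333,13,2.66666666666667,-1,51.6666666666667,74.6666666666667,68,-1.33333333333333,-0.333333333333333,4.66666666666667,9,-0.666666666666667,-3,0.333333333333333,-3,-1.66666666666667
"OSN08","G08",-3.33333333333333,2.33333333333333,3.33333333333333,3,4.66666666666667,11.6666666666667,0.333333333333333,0.333333333333333,14,5.33333333333333,17,2,75.3333333333333,-0.333333333333333,47,-1,38
"OSN09","G09",3.33333333333333,0.333333333333333,-1,12.6666666666667,7,8.66666666666667,9.66666666666667,4.33333333333333,1.33333333333333,70.3333333333333,8.66666666666667,60.3333333333333,8,49.3333333333333,13.6666666666667,23.6666666666667,-1.33333333333333
"OSN10","G10",26.6666666666667,54.3333333333333,34.3333333333333,41.3333333333333,76,46.6666666666667,84.6666666666667,1.66666666666667,1,4.66666666666667,3,-2.66666666666667,3.66666666666667,2,3,-1.33333333333333,9.33333333333333
"OSN11","G11",2.33333333333333,1,-4,9.66666666666667,-1.33333333333333,1.33333333333333,5.33333333333333,4.33333333333333,16.6666666666667,-1.66666666666667,95,3.33333333333333,5,-5,86.6666666666667,-0.666666666666667,84.3333333333333
"OSN12","G12",8.33333333333333,5.33333333333333,7.33333333333333,9.66666666666667,11.6666666666667,5.33333333333333,5.33333333333333,4.66666666666667,2.33333333333333,54,5.33333333333333,3.33333333333333,8.33333333333333,10,2,13.3333333333333,8
"OSN13","G13",2,41,89.3333333333333,63.6666666666667,76.3333333333333,99.3333333333333,57.3333333333333,25.3333333333333,4,4.66666666666667,6.66666666666667,6,3.66666666666667,2.66666666666667,1.66666666666667,3.66666666666667,6.33333333333333
"OSN14","G14",16,5.33333333333333,4,11.3333333333333,5,5,10.3333333333333,3,7,2.66666666666667,26.6666666666667,4.33333333333333,67.6666666666667,7.66666666666667,70,5,49.6666666666667
"OSN15","G15",1,10,5.66666666666667,10,0.666666666666667,5.66666666666667,2.66666666666667,-1.66666666666667,5,59.6666666666667,4,66.3333333333333,-0.333333333333333,44,5.33333333333333,53.6666666666667,-2.66666666666667
"OSN16","G16",44,64.6666666666667,47.3333333333333,67,20,26.6666666666667,85.3333333333333,5.33333333333333,-4.33333333333333,9.66666666666667,3,8.66666666666667,7.33333333333333,2,9.33333333333333,3,3.33333333333333
"OSN18","G18",2.66666666666667,4.33333333333333,4.33333333333333,5,12,2.33333333333333,4,8.66666666666667,0,39.6666666666667,12.3333333333333,34,11.6666666666667,67.6666666666667,-1,17.6666666666667,6.33333333333333
"OSN19","G19",23.6666666666667,56.6666666666667,17,23.3333333333333,23,45.3333333333333,85.6666666666667,32.6666666666667,4.66666666666667,7,8,4.66666666666667,1,5,1.66666666666667,4,8
"OSN20","G20",5.33333333333333,2,11,7.33333333333333,-2,5.33333333333333,6,0.666666666666667,87,-0.333333333333333,3.33333333333333,5.33333333333333,52,1.66666666666667,33.6666666666667,0,27.6666666666667
"OSN21","G21",2.33333333333333,6.33333333333333,-2.33333333333333,8,10.6666666666667,0,4.33333333333333,0,-1,75,-3,4.66666666666667,7,91,1,5,5.33333333333333
"OSN22","G22",-0.333333333333333,21.3333333333333,82,24.3333333333333,84.6666666666667,80,-0.666666666666667,29,5,2.66666666666667,1.66666666666667,2.66666666666667,5.66666666666667,0,1.66666666666667,-3,-3
"OSN23","G23",8.66666666666667,7.33333333333333,5.33333333333333,8,4.66666666666667,3.66666666666667,9,7,27,9.66666666666667,29.6666666666667,3,72,2.66666666666667,51.3333333333333,7,23
"OSN24","G24",1.66666666666667,0.333333333333333,3.33333333333333,4.33333333333333,6.66666666666667,6.33333333333333,9,3.66666666666667,1.66666666666667,16.3333333333333,3,60,1,-1.66666666666667,-0.666666666666667,6,-0.333333333333333
"OSN25","G25",24.6666666666667,50,31.3333333333333,6.33333333333333,71,72,58,79,4,7,7,3,0,3.66666666666667,2.66666666666667,8.33333333333333,8
"OSN26","G26",7,3,-0.666666666666667,5.33333333333333,2,9.66666666666667,15.6666666666667,6.33333333333333,47,11.3333333333333,49,9.66666666666667,44,5.66666666666667,21.6666666666667,1,21
"OSN27","G27",4.33333333333333,5.33333333333333,2.66666666666667,5.33333333333333,6.33333333333333,18,2,3.66666666666667,3.66666666666667,74.3333333333333,1.66666666666667,24.3333333333333,4.66666666666667,29,11.3333333333333,59.6666666666667,7.66666666666667
"OSN28","G28",93.6666666666667,19,6,54,53.3333333333333,6.66666666666667,89.6666666666667,75.3333333333333,6.33333333333333,4,6.66666666666667,10,2.66666666666667,8.66666666666667,11,5,3
"OSN29","G29",5,-0.333333333333333,3.33333333333333,0.666666666666667,6,2.66666666666667,4,6,11.6666666666667,2.33333333333333,61,10.6666666666667,37,6,55.3333333333333,10.3333333333333,56.3333333333333
"OSN30","G30",4,5.33333333333333,0,-0.333333333333333,-1.33333333333333,11.3333333333333,7.33333333333333,5.33333333333333,4.66666666666667,77.3333333333333,-1,90,4.33333333333333,13,11.6666666666667,78.6666666666667,-0.333333333333333
"OSN31","G31",36.3333333333333,15,80.6666666666667,54.3333333333333,30.3333333333333,5,71.6666666666667,44.6666666666667,8,4,8,5.33333333333333,0.666666666666667,-1,3.33333333333333,0.666666666666667,5.66666666666667
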