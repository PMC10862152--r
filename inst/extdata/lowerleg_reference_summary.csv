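variable,sex,band,n,mean,sd,min,max
age,boy,infant,4,0.18,0.05,0.14,0.26
age,girl,infant,4,0.21,0.04,0.18,0.26
age,boy,5-7.5,25,6.5,0.78,5.36,7.46
age,girl,5-7.5,17,6.47,0.69,5.09,7.48
age,boy,7.5-10,30,8.62,0.68,7.57,9.87
age,girl,7.5-10,24,8.82,0.67,7.52,9.97
age,boy,10-12.5,43,11.13,0.79,10.02,12.42
age,girl,10-12.5,24,11.1,0.67,10.07,12.32
age,boy,12.5-15,19,13.75,0.81,12.5,14.94
age,girl,12.5-15,18,13.79,0.81,12.65,14.97
body_mass,boy,infant,4,6.7,0.8,6,7.9
body_mass,girl,infant,4,5.8,1.3,4.2,6.9
body_mass,boy,5-7.5,25,23.5,3.6,17,32.7
body_mass,girl,5-7.5,17,22.8,3.4,17.3,30.2
body_mass,boy,7.5-10,30,31.1,6.5,21.3,53.5
body_mass,girl,7.5-10,24,31,6.6,20.5,46
body_mass,boy,10-12.5,43,39.3,9.1,24,76.4
body_mass,girl,10-12.5,24,38.6,6.6,26.9,53.3
body_mass,boy,12.5-15,19,53.1,12.5,37,81.9
body_mass,girl,12.5-15,18,53.6,8.1,39.8,73.1
height,boy,infant,4,59.1,2.4,57,62.5
height,girl,infant,4,58.8,3.6,54.2,63
height,boy,5-7.5,25,120.9,6.7,108.9,133.6
height,girl,5-7.5,17,120.7,6.7,108.4,131.6
height,boy,7.5-10,30,135.2,6.8,124.8,152
height,girl,7.5-10,24,134.2,7.3,123.2,155.7
height,boy,10-12.5,43,147.7,8.7,130,172
height,girl,10-12.5,24,146.2,7.8,132,159
height,boy,12.5-15,19,164.4,9.5,152,179.7
height,girl,12.5-15,18,163.8,5,157.5,179.4
fibula_length,boy,infant,4,9,0.7,8.2,9.9
fibula_length,girl,infant,4,9,0.5,8.6,9.7
fibula_length,boy,5-7.5,25,25.3,2,21.8,30
fibula_length,girl,5-7.5,17,25.6,1.5,22.9,28.2
fibula_length,boy,7.5-10,30,29.6,2,26.4,33.9
fibula_length,girl,7.5-10,24,29.2,2.1,26.7,36.2
fibula_length,boy,10-12.5,43,32.9,2.4,27.9,39.5
fibula_length,girl,10-12.5,24,32.3,1.8,29.3,35.5
fibula_length,boy,12.5-15,19,36.9,2,33.6,40.5
fibula_length,girl,12.5-15,18,36.1,1.6,33.9,40.8
tibia_length,boy,infant,4,10.1,0.5,9.6,10.9
tibia_length,girl,infant,4,9.7,0.6,9.2,10.5
tibia_length,boy,5-7.5,25,26.1,2,22.5,31
tibia_length,girl,5-7.5,17,26.2,1.5,23.7,28.9
tibia_length,boy,7.5-10,30,30.2,2.1,26.9,34.6
tibia_length,girl,7.5-10,24,30.1,2.3,27.2,37.6
tibia_length,boy,10-12.5,43,33.9,2.6,28.9,41.5
tibia_length,girl,10-12.5,24,33.5,1.9,30.2,37
tibia_length,boy,12.5-15,19,38.1,2.3,34.6,43
tibia_length,girl,12.5-15,18,37.4,1.5,34.9,41.5
LG,boy,infant,4,2.4,0.7,1.8,3.3
LG,girl,infant,4,2.2,0.5,1.7,2.9
LG,boy,5-7.5,25,31.3,7,23.1,48.2
LG,girl,5-7.5,17,27.4,6.8,17.6,39.9
LG,boy,7.5-10,30,46.2,13.9,23,92.5
LG,girl,7.5-10,24,41.2,11,22,67.3
LG,boy,10-12.5,43,61.9,20.1,32.4,133.6
LG,girl,10-12.5,24,58.2,13.1,33.6,81.4
LG,boy,12.5-15,19,94.6,20.9,66.6,131.4
LG,girl,12.5-15,18,93.4,25.3,49.7,164.3
MG,boy,infant,4,3.2,0.9,2.3,4.3
MG,girl,infant,4,3,0.6,2.3,3.6
MG,boy,5-7.5,25,56.7,13.2,40.3,85.6
MG,girl,5-7.5,17,54.1,13,37.5,84.3
MG,boy,7.5-10,30,85.3,27.8,43.6,165.7
MG,girl,7.5-10,24,81,18.5,45.2,112.5
MG,boy,10-12.5,43,105.5,29.4,70,227.6
MG,girl,10-12.5,24,110.7,25.2,61.1,166.2
MG,boy,12.5-15,19,176.8,52,116.2,299.2
MG,girl,12.5-15,18,162.8,45.4,104.6,278.9
SOL,boy,infant,4,6.7,0.6,6,7.4
SOL,girl,infant,4,6.3,1.1,4.7,7.1
SOL,boy,5-7.5,25,117.9,24.7,88.1,173.8
SOL,girl,5-7.5,17,112.6,23.9,75.6,152.2
SOL,boy,7.5-10,30,173.9,48.1,101.3,309.2
SOL,girl,7.5-10,24,167.6,49.1,96.3,323
SOL,boy,10-12.5,43,224.7,67.7,137.7,510
SOL,girl,10-12.5,24,223.5,48.4,148.3,326.1
SOL,boy,12.5-15,19,346.5,101.9,226.4,607.3
SOL,girl,12.5-15,18,317,56.3,200.6,453.5
TA,boy,infant,4,3.6,0.8,2.8,4.5
TA,girl,infant,4,3.2,0.6,2.4,3.7
TA,boy,5-7.5,25,33.1,7.1,22.1,48.4
TA,girl,5-7.5,17,30.5,6.5,21.3,39.7
TA,boy,7.5-10,30,46.8,10.8,30,72.3
TA,girl,7.5-10,24,43.6,10.5,27.8,72.5
TA,boy,10-12.5,43,61.6,16.6,39.2,127.1
TA,girl,10-12.5,24,61,13.7,35.4,93.7
TA,boy,12.5-15,19,94.2,24.1,58.3,139.1
TA,girl,12.5-15,18,82.4,16.2,58.3,111.2
TP,boy,infant,4,3.7,0.3,3.3,4
TP,girl,infant,4,3.1,0.4,2.6,3.3
TP,boy,5-7.5,25,33.6,6.8,24.8,52.2
TP,girl,5-7.5,17,32.1,6.7,21.8,41.1
TP,boy,7.5-10,30,50.7,11.5,29.8,81.5
TP,girl,7.5-10,24,45.1,10.2,27.7,74.4
TP,boy,10-12.5,43,66.2,16.1,41.2,125.9
TP,girl,10-12.5,24,62.1,10.6,42.7,81.8
TP,boy,12.5-15,19,96.2,21.1,67,139.7
TP,girl,12.5-15,18,81,12.7,59.2,105.2
EEP,boy,infant,4,3.6,0.5,3.2,4.3
EEP,girl,infant,4,3.1,0.3,2.7,3.4
EEP,boy,5-7.5,25,29.5,5.8,21,43
EEP,girl,5-7.5,17,27,4.6,19.4,36.6
EEP,boy,7.5-10,30,41,8.5,26.9,60.1
EEP,girl,7.5-10,24,36.2,7.5,27.5,61.9
EEP,boy,10-12.5,43,51.8,13.2,30.4,103.1
EEP,girl,10-12.5,24,48.7,9.3,34.9,70.1
EEP,boy,12.5-15,19,76.3,16.5,54.5,103.1
EEP,girl,12.5-15,18,63.5,10.5,46.4,83.9
PBL,boy,infant,4,3.4,0.8,2.6,4.5
PBL,girl,infant,4,3.1,0.7,2.2,3.7
PBL,boy,5-7.5,25,37.6,7.9,27,55.3
PBL,girl,5-7.5,17,34.8,6.8,24,45.2
PBL,boy,7.5-10,30,53.1,12.4,33.3,89.5
PBL,girl,7.5-10,24,47.8,12.6,28.2,84.8
PBL,boy,10-12.5,43,68.6,19.3,44.3,143.6
PBL,girl,10-12.5,24,66.1,12.8,46.6,93.4
PBL,boy,12.5-15,19,103.7,28.7,63.2,158.2
PBL,girl,12.5-15,18,90.4,15.5,59.6,119.8
POP,boy,infant,4,0.6,0.2,0.4,0.9
POP,girl,infant,4,0.6,0.1,0.5,0.7
POP,boy,5-7.5,25,7.3,1.6,4.8,11.4
POP,girl,5-7.5,17,6.2,1.2,3.9,8.1
POP,boy,7.5-10,30,10,2.3,6.8,17.2
POP,girl,7.5-10,24,8.6,1.4,6.6,12.4
POP,boy,10-12.5,43,13.1,3.3,7.3,25.4
POP,girl,10-12.5,24,11.7,1.8,8.6,14.8
POP,boy,12.5-15,19,18.2,3.5,12.3,25.4
POP,girl,12.5-15,18,15.3,2.5,11,20
FDL,boy,infant,4,1.1,0.2,0.9,1.2
FDL,girl,infant,4,0.6,0.2,0.3,0.8
FDL,boy,5-7.5,25,11.4,2.2,7.4,15.8
FDL,girl,5-7.5,17,11,2.9,6.8,17.6
FDL,boy,7.5-10,30,17,3.8,10.2,23.5
FDL,girl,7.5-10,24,15,3.4,10.6,25.1
FDL,boy,10-12.5,43,21.7,4.6,15.5,40.1
FDL,girl,10-12.5,24,19.4,3,14.2,25.8
FDL,boy,12.5-15,19,29.8,6.4,19.7,44.3
FDL,girl,12.5-15,18,24.3,5.1,16,31.8
FHL,boy,infant,4,2.7,0.5,2.2,3.4
FHL,girl,infant,4,2.1,0.7,1.4,3
FHL,boy,5-7.5,25,20.8,4.1,13.5,29.2
FHL,girl,5-7.5,17,19.7,2.8,14.6,25
FHL,boy,7.5-10,30,30.7,7.1,18.5,47.9
FHL,girl,7.5-10,24,26.8,5.7,19.4,44
FHL,boy,10-12.5,43,39.4,9.3,26.7,80.2
FHL,girl,10-12.5,24,36.9,5.7,26.6,45.8
FHL,boy,12.5-15,19,53.5,9.2,39,71.2
FHL,girl,12.5-15,18,46.4,7.5,32.7,64.5
TSURAE,boy,infant,4,12.3,2,10.3,14.4
TSURAE,girl,infant,4,11.6,1.8,9.1,13.3
TSURAE,boy,5-7.5,25,205.9,43.9,152.1,303.4
TSURAE,girl,5-7.5,17,194.1,41.9,135.1,267.5
TSURAE,boy,7.5-10,30,305.4,88.1,172,567.4
TSURAE,girl,7.5-10,24,289.8,76.4,163.5,502.7
TSURAE,boy,10-12.5,43,392.1,115.2,244,870.1
TSURAE,girl,10-12.5,24,392.4,84.4,243,570.7
TSURAE,boy,12.5-15,19,617.9,169,416.7,973
TSURAE,girl,12.5-15,18,573.2,120.2,354.9,896.7
TOTAL,boy,infant,4,31,4.9,26.2,36.3
TOTAL,girl,infant,4,27.4,4,21.6,30.4
TOTAL,boy,5-7.5,25,379.1,75.9,282.7,556.6
TOTAL,girl,5-7.5,17,355.3,68.7,248.3,475.3
TOTAL,boy,7.5-10,30,554.8,139.1,340.9,955.8
TOTAL,girl,7.5-10,24,512.9,123.7,327.1,877.8
TOTAL,boy,10-12.5,43,714.4,189.7,449.8,1414.2
TOTAL,girl,10-12.5,24,698.3,135.7,456.3,990.9
TOTAL,boy,12.5-15,19,1089.7,263.8,733.7,1606.7
TOTAL,girl,12.5-15,18,976.5,175.1,639.9,1432.6
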