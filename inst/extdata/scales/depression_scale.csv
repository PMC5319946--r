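index,lower,upper,lo_closed,hi_closed,points
weight,0,300,TRUE,FALSE,1
weight,300,310,TRUE,FALSE,2
weight,310,320,TRUE,FALSE,3
weight,320,330,TRUE,FALSE,4
weight,330,340,TRUE,FALSE,5
weight,340,350,TRUE,FALSE,5
weight,350,360,TRUE,FALSE,5
weight,360,370,TRUE,FALSE,4
weight,370,380,TRUE,FALSE,3
weight,380,390,TRUE,FALSE,2
weight,390,Inf,TRUE,FALSE,1
sucrose,0,50,TRUE,FALSE,0
sucrose,50,55,TRUE,FALSE,1
sucrose,55,60,TRUE,FALSE,2
sucrose,60,65,TRUE,FALSE,3
sucrose,65,70,TRUE,FALSE,4
sucrose,70,75,TRUE,FALSE,5
sucrose,75,80,TRUE,FALSE,6
sucrose,80,85,TRUE,FALSE,7
sucrose,85,90,TRUE,FALSE,8
sucrose,90,95,TRUE,FALSE,9
sucrose,95,Inf,TRUE,FALSE,10
distance,0,0,TRUE,TRUE,0
distance,0,5,FALSE,FALSE,1
distance,5,10,TRUE,FALSE,2
distance,10,15,TRUE,FALSE,3
distance,15,20,TRUE,FALSE,4
distance,20,Inf,TRUE,FALSE,5
rearing,0,0,TRUE,TRUE,0
rearing,0,5,FALSE,FALSE,1
rearing,5,10,TRUE,FALSE,2
rearing,10,15,TRUE,FALSE,3
rearing,15,20,TRUE,FALSE,4
rearing,20,Inf,TRUE,FALSE,5
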