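index,lower,upper,lo_closed,hi_closed,points
id,0,1,TRUE,FALSE,0
id,1,5,TRUE,FALSE,1
id,5,10,TRUE,FALSE,2
id,10,15,TRUE,FALSE,3
id,15,20,TRUE,FALSE,4
id,20,25,TRUE,FALSE,5
id,25,30,TRUE,FALSE,6
id,30,Inf,TRUE,FALSE,7
it,0,1,TRUE,FALSE,0
it,1,5,TRUE,FALSE,1
it,5,10,TRUE,FALSE,2
it,10,15,TRUE,FALSE,3
it,15,20,TRUE,FALSE,4
it,20,25,TRUE,FALSE,5
it,25,30,TRUE,FALSE,6
it,30,Inf,TRUE,FALSE,7
ot,0,1,TRUE,FALSE,0
ot,1,5,TRUE,FALSE,1
ot,5,10,TRUE,FALSE,2
ot,10,15,TRUE,FALSE,3
ot,15,20,TRUE,FALSE,4
ot,20,25,TRUE,FALSE,5
ot,25,30,TRUE,FALSE,6
ot,30,Inf,TRUE,FALSE,7
oe,0,1,TRUE,FALSE,0
oe,1,20,TRUE,FALSE,1
oe,20,25,TRUE,FALSE,2
oe,25,30,TRUE,FALSE,3
oe,30,35,TRUE,FALSE,4
oe,35,40,TRUE,FALSE,5
oe,40,45,TRUE,FALSE,6
oe,45,Inf,TRUE,FALSE,7
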