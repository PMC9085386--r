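"","AVBL","AVBR","PVCL","PVCR","AVAL","AVAR","AVDL","AVDR","AVEL","AVER"
"AVBL",0,1,6,3,4,0,0,0,3,0
"AVBR",3,0,3,6,0,4,0,0,0,3
"PVCL",0,0,1,5,5,0,0,0,3,0
"PVCR",0,0,3,0,0,5,0,0,0,3
"AVAL",4,3,4,0,0,7,6,3,6,5
"AVAR",3,4,0,4,9,0,3,6,5,6
"AVDL",3,0,0,0,1,0,0,3,0,0
"AVDR",0,3,0,0,0,1,3,0,0,0
"AVEL",3,0,0,0,4,4,0,0,0,1
"AVER",0,3,0,0,4,4,0,0,0,0
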