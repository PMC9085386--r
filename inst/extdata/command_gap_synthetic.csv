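"","AVBL","AVBR","PVCL","PVCR","AVAL","AVAR","AVDL","AVDR","AVEL","AVER"
"AVBL",0,8,0,0,0,0,0,0,0,0
"AVBR",8,0,0,0,0,0,0,0,0,0
"PVCL",0,0,0,27,15,0,0,0,0,0
"PVCR",0,0,27,0,0,15,0,0,0,0
"AVAL",0,0,15,0,0,8,5,0,0,0
"AVAR",0,0,0,15,8,0,0,5,0,0
"AVDL",0,0,0,0,5,0,0,4,0,0
"AVDR",0,0,0,0,0,5,4,0,0,0
"AVEL",0,0,0,0,0,0,0,0,0,1
"AVER",0,0,0,0,0,0,0,0,1,0
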