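trial,category,genus,species,count
1,target,Culex,Culex pipiens,1261
1,target,Aedes,Aedes albopictus,270
1,target,Aedes,Aedes caspius,39
1,nontarget_mosquito,Culiseta,Culiseta longiareolata,94
1,nontarget_mosquito,Coquillettidia,Coquillettidia richiardii,1
1,other_insect,,Non-culicidae insects,3188
2,target,Culex,Culex pipiens,1387
2,target,Aedes,Aedes albopictus,543
2,nontarget_mosquito,Culiseta,Culiseta longiareolata,39
2,other_insect,,Non-culicidae insects,2125
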