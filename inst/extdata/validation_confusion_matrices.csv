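threshold,model,tp,fp,fn,tn
2.5,NN,10,47,2,250
2.5,DT,10,20,2,277
2.5,RBS,10,42,2,255
2.5,SVM,8,18,4,279
3.0,NN,12,52,0,245
3.0,DT,11,18,1,279
3.0,RBS,11,29,1,268
3.0,SVM,10,12,2,285
3.09290,NN,12,59,0,238
3.09290,DT,11,26,1,271
3.09290,RBS,12,35,0,262
3.09290,SVM,10,13,2,284
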