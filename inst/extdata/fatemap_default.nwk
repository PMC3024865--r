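(((((trachea:1,lung:1)PrimitiveGut1:1,(pancreas:1,liver:1)PrimitiveGut2:1,(thymus:1,prostate:1)PrimitiveGut3:1)PrimitiveGut:1,thyroid:2)Endoderm:1,((skin:1,skeletalmuscle:1)ParaxialMesoderm:2,((uterus:1,kidney:1)KU:1,(testis:1,ovary:1)Gonad:1)IntermediateMesoderm:1,(heart:1,adrenalgland:1)LateralPlateMesoderm:2)Mesoderm:1)Mesendoderm:1,((dorsalrootganglion:1,trigeminalganglion:1)NeuralCrest:3,(((prefrontalcortex:1,amygdala:1,pituitary:1,hypothalamus:1)Brain1:1,(cerebellum:1,olfactorybulb:1)Brain2:1)Brain:1,spinalcord:3)NeuralTube:1)Ectoderm:1)Zygote;
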