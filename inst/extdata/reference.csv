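taxon,specimen_id,element,tissue,n_onar,mean_onar,disp_onar,disp_kind_onar,n_har,mean_har,disp_har,disp_kind_har,n_bones,source
Naumann's elephant,PLN01Tp,Tib ant mid,SO,18,224893.3,27974.9,SE,18,5584.1,987.6,SE,1,this-study
Pleistocene elephant fossil,EKZ97Fa,Fem ant mid,SO,10,175852.0,23663.3,SE,10,3711.8,656.2,SE,1,this-study
Asian elephant,Ele01Fp,Fem ant mid,SO,5,263151.7,2045.0,SE,5,21490.6,76.8,SE,1,this-study
Human,Homo01Ha,Hum ant mid,SO,30,30722.8,2488.9,SE,30,1975.1,202.4,SE,1,sawada
Human,Homo03Ha,Hum ant mid,SO,39,31463.8,1687.9,SE,39,2040.9,143.3,SE,1,sawada
Human,Homo01Fa,Fem ant mid,SO,54,41846.8,2177.3,SE,54,2524.5,161.9,SE,1,sawada
Human,Homo02Fa,Fem ant mid,SO,55,33931.6,1648.9,SE,55,1734.3,134.1,SE,1,sawada
Human,Homo04Fa,Fem ant mid,SO,46,35774.2,1650.4,SE,46,2336.2,135.7,SE,1,sawada
Human,Homo05Fa,Fem ant mid,SO,22,36560.1,2572.6,SE,22,1748.7,210.0,SE,1,sawada
Human,Homo06Fa,Fem ant mid,SO,26,49038.7,4502.8,SE,26,2334.5,260.4,SE,1,sawada
Human,HomoPf01,Fem ant mid,SO,1078,35988.9,497.2,SE,1078,1938.0,41.8,SE,15,external-literature
Human,HomoPf02,Fem ant mid,SO,996,44532.9,711.2,SE,996,3667.4,123.6,SE,20,external-literature
Human,HomoPf03,Fem ant mid,SO,1023,35057.4,533.0,SE,1023,3207.2,59.9,SE,20,external-literature
Macaque,Mac01Fa,Fem ant mid,SO,12,36154.1,3087.3,SE,12,1317.3,174.7,SE,1,this-study
Macaque,MacHa01,Fem mid,SO,NA,23984.0,6324.2,SD,NA,1442.1,469.0,SD,41,external-literature
Macaque,MacHa02,Fem mid,SO,NA,23583.4,4740.2,SD,NA,1523.2,531.9,SD,34,external-literature
Leporid,Lep01Hp,Hum post mid,SO,6,10869.5,773.8,SE,6,168.5,31.1,SE,1,this-study
Leporid,Lep01Fl,Fem lat mid,SO,13,11136.7,1292.2,SE,13,165.8,23.3,SE,1,this-study
Rabbit,RabMa,Fem mid,SO,50,8340.0,460.3,SE,50,367.5,32.5,SE,10,external-literature
Wild boar,Sus01Ha,Hum ant mid,SO,87,19673.2,767.1,SE,87,646.0,30.8,SE,1,sawada
Wild boar,Sus02Ha,Hum ant mid,SO,28,25294.5,2087.0,SE,28,463.7,31.5,SE,1,sawada
Wild boar,Sus01Fa,Fem ant mid,SO,29,25740.1,1403.7,SE,29,827.7,66.8,SE,1,sawada
Wild boar,Sus02Fa,Fem ant mid,SO,11,24932.9,3243.8,SE,11,680.7,116.6,SE,1,sawada
Sika deer,Cer02Ha,Hum ant mid,SO;PF,51,19076.6,872.5,SE,51,469.4,19.5,SE,1,this-study
Sika deer,Cer03Ha,Hum ant mid,SO;PF,30,20618.6,1286.8,SE,30,503.5,31.6,SE,1,this-study
Sika deer,Cer01Ra,Rad ant mid,SO,49,12144.2,620.6,SE,49,263.6,13.4,SE,1,this-study
Sika deer,Cer01Fa,Fem ant mid,PF,NA,NA,NA,NA,NA,NA,NA,NA,1,this-study
Sika deer,Cer05Fa,Fem ant mid,PF,NA,NA,NA,NA,NA,NA,NA,NA,1,this-study
Sika deer,Cer01Fp,Fem post mid,SO,39,17965.2,1412.5,SE,39,506.8,35.4,SE,1,sawada
Sika deer,Cer02Fp,Fem post mid,SO,58,28138.8,1272.2,SE,58,575.0,24.7,SE,1,sawada
Sika deer,Cer03Fp,Fem post mid,SO,48,22522.9,1407.0,SE,48,722.2,45.8,SE,1,sawada
Sika deer,Cer01Ta,Tib ant mid,SO;PF,66,12920.0,505.7,SE,66,408.9,20.9,SE,1,this-study
Sika deer,Cer04Ta,Tib ant mid,PF,NA,NA,NA,NA,NA,NA,NA,NA,1,this-study
Ancient sika deer,CPR91Fp,Fem post mid,SO,37,23922.7,2068.4,SE,37,459.0,40.7,SE,1,this-study
Ancient sika deer,CPR92Ta,Tib ant mid,SO,117,15037.8,492.2,SE,117,326.5,13.8,SE,1,this-study
Reindeer,Ran01Fp,Fem post mid,SO,40,17072.0,1080.2,SE,40,272.2,19.5,SE,1,this-study
Japanese serow,Cap01Fa,Fem ant mid,SO,32,26140.1,1461.8,SE,32,485.8,36.8,SE,1,sawada
Yabe's giant deer,SMY01M,Mand bas,SO,24,40086.5,3212.8,SE,24,350.0,53.3,SE,1,this-study
Yabe's giant deer,SMY02Ra,Rad ant mid,PF,NA,NA,NA,NA,NA,NA,NA,NA,1,this-study
Cattle,Bos01Ha,Hum ant mid,PF,NA,NA,NA,NA,NA,NA,NA,NA,1,this-study
Cattle,Bos04Ha,Hum ant mid,SO,71,43209.7,1740.1,SE,71,591.4,28.7,SE,1,sawada
Cattle,Bos05Ha,Hum ant mid,SO,30,25216.9,1603.3,SE,30,512.1,22.5,SE,1,this-study
Cattle,Bos01Ra,Rad ant mid,SO;PF,13,29406.6,1959.2,SE,13,671.8,50.7,SE,1,this-study
Cattle,Bos02Fa,Fem ant mid,SO,25,31532.4,2000.3,SE,25,699.6,56.6,SE,1,sawada
Cattle,Bos03Fa,Fem ant mid,SO,16,28061.3,2700.5,SE,16,714.8,84.5,SE,1,sawada
Cattle,BosMa,Fem mid,SO,160,31725.4,889.2,SE,160,1196.7,51.1,SE,8,external-literature
Bison,Bis01Fp,Fem post mid,SO,88,24199.5,1039.4,SE,88,770.3,28.8,SE,1,this-study
Japanese marten,Mar01Ha,Hum ant mid,SO,10,11766.2,1438.9,SE,10,197.5,35.3,SE,1,this-study
Dog,Can01Fa,Fem ant mid,SO,26,12789.2,1017.4,SE,26,298.2,32.0,SE,1,this-study
Dog,Can01Ta,Tib ant mid,SO,65,15291.4,609.8,SE,65,273.3,16.3,SE,1,this-study
Raccoon dog,Nyc01Fa,Fem ant mid,PF,NA,NA,NA,NA,NA,NA,NA,NA,1,this-study
Raccoon dog,Nyc01Fp,Fem post mid,SO,13,22022.3,3202.3,SE,13,480.1,53.5,SE,1,this-study
Red fox,Vul01M,Mand bas,SO,21,32937.9,2345.5,SE,21,294.6,31.0,SE,1,this-study
Leopard,Pan01Fa,Fem ant mid,SO,26,29351.5,4010.7,SE,26,772.3,68.3,SE,1,this-study
Brown bear,Urs01Ha,Hum ant mid,SO,114,26356.1,1049.6,SE,114,719.5,27.8,SE,1,sawada
Brown bear,Urs01Ra,Rad ant mid,SO,109,29614.9,1109.3,SE,109,942.1,38.3,SE,1,this-study
Brown bear,Urs01Fa,Fem ant mid,SO,131,22203.2,722.9,SE,131,637.3,27.8,SE,1,sawada
Brown bear,Urs01Ta,Tib ant mid,SO,138,22496.6,694.5,SE,138,715.9,30.3,SE,1,sawada
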