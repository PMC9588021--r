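feature,wood_class,low,high
monolignol_G,softwood,95,100
monolignol_S,softwood,0,1
monolignol_H,softwood,0,5
beta-O-4,softwood,45,50
beta-beta,softwood,2,6
beta-5,softwood,9,12
5-5/dbdo,softwood,2.5,11
4-O-5,softwood,2,8
monolignol_G,hardwood,25,50
monolignol_S,hardwood,45,75
monolignol_H,hardwood,0,8
beta-O-4,hardwood,50,65
beta-beta,hardwood,3,16
beta-5,hardwood,3,11
5-5/dbdo,hardwood,0,4
4-O-5,hardwood,2,7
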