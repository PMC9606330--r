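synonym,ingredient,class,region
bevacizumab,bevacizumab,anti_VEGF_mAb,both
avastin,bevacizumab,anti_VEGF_mAb,both
mvasi,bevacizumab,anti_VEGF_mAb,FDA
zirabev,bevacizumab,anti_VEGF_mAb,FDA
ramucirumab,ramucirumab,anti_VEGFR_mAb,FDA
cyramza,ramucirumab,anti_VEGFR_mAb,FDA
aflibercept,aflibercept,VEGF_trap,FDA
ziv-aflibercept,aflibercept,VEGF_trap,FDA
zaltrap,aflibercept,VEGF_trap,FDA
eylea,aflibercept,VEGF_trap,FDA
sunitinib,sunitinib,TKI,both
sutent,sunitinib,TKI,both
su11248,sunitinib,TKI,both
lenvatinib,lenvatinib,TKI,both
lenvima,lenvatinib,TKI,both
e7080,lenvatinib,TKI,both
nintedanib,nintedanib,TKI,FDA
ofev,nintedanib,TKI,FDA
vargatef,nintedanib,TKI,FDA
bibf 1120,nintedanib,TKI,FDA
pazopanib,pazopanib,TKI,both
votrient,pazopanib,TKI,both
gw786034,pazopanib,TKI,both
cabozantinib,cabozantinib,TKI,FDA
cabometyx,cabozantinib,TKI,FDA
cometriq,cabozantinib,TKI,FDA
xl184,cabozantinib,TKI,FDA
sorafenib,sorafenib,TKI,both
nexavar,sorafenib,TKI,both
bay 43-9006,sorafenib,TKI,both
axitinib,axitinib,TKI,both
inlyta,axitinib,TKI,both
ag-013736,axitinib,TKI,both
regorafenib,regorafenib,TKI,both
stivarga,regorafenib,TKI,both
bay 73-4506,regorafenib,TKI,both
apatinib,apatinib,TKI,NMPA
aitan,apatinib,TKI,NMPA
yn968d1,apatinib,TKI,NMPA
vandetanib,vandetanib,TKI,FDA
caprelsa,vandetanib,TKI,FDA
zd6474,vandetanib,TKI,FDA
tivozanib,tivozanib,TKI,FDA
fotivda,tivozanib,TKI,FDA
av-951,tivozanib,TKI,FDA
cediranib,cediranib,TKI,FDA
recentin,cediranib,TKI,FDA
azd2171,cediranib,TKI,FDA
erdafitinib,erdafitinib,TKI,FDA
balversa,erdafitinib,TKI,FDA
jnj-42756493,erdafitinib,TKI,FDA
fruquintinib,fruquintinib,TKI,NMPA
elunate,fruquintinib,TKI,NMPA
hmpl-013,fruquintinib,TKI,NMPA
vatalanib,vatalanib,TKI,FDA
ptk787,vatalanib,TKI,FDA
zk222584,vatalanib,TKI,FDA
anlotinib,anlotinib,TKI,NMPA
focus v,anlotinib,TKI,NMPA
al3818,anlotinib,TKI,NMPA
recombinant human endostatin,recombinant human endostatin,other_antiangiogenic,NMPA
endostar,recombinant human endostatin,other_antiangiogenic,NMPA
rh-endostatin,recombinant human endostatin,other_antiangiogenic,NMPA
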