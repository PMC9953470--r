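# ORd endocardial drug-free steady state, CL 2000 ms, 10000 beats
# model_version: ORd2011-dutta2017-v1
v -86.406719842756274
nai 6.4577076722200966
nass 6.4577822750157923
ki 137.30258660873443
kss 137.30256947530756
cai 8.3971651066165268e-05
cass 8.2017712461013604e-05
cansr 1.5713744913299181
cajsr 1.5713885881416283
m 0.0086211268779728782
hf 0.64019130808081459
hs 0.64019171404211273
j 0.6401933609510384
hsp 0.39113784927557377
jp 0.6401940538046923
mL 0.00025488252265368038
hL 0.45979554555189006
hLp 0.26312341330274547
a 0.0011147336799364653
iF 0.99941068155362656
iS 0.8575938505326528
ap 0.00056801858946420227
iFp 0.99941068137377553
iSp 0.88935938319163921
d 3.4129842097234978e-09
ff 0.99999998595257111
fs 0.96469430498512332
fcaf 0.999999985952569
fcas 0.99999996348519749
jca 0.99999998585600891
nca 0.0024023084966933407
ffp 0.99999998595264983
fcafp 0.99999998595264461
xrf 1.0135517483538583e-05
xrs 0.18715515256633902
xs1 0.15387622411144908
xs2 0.00023047391704145054
xk1 0.99715284856818531
Jrelnp 7.3466857611761399e-07
Jrelp 9.1832144521154048e-07
CaMKt 0.005043483443391489
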