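drug,factor_mg_per_mg
imipramine,1.0
amitriptyline,1.0
clomipramine,1.25
fluoxetine,3.75
paroxetine,4.4
sertraline,1.5
citalopram,3.9
escitalopram,8.3
venlafaxine,1.0
duloxetine,2.5
mirtazapine,6.0
trazodone,0.37
bupropion,0.5
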