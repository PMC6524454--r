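surface	category	concept
infarct	SBI_FINDING	SBI
infarcts	SBI_FINDING	SBI
infarctions	SBI_FINDING	SBI
infarction	SBI_FINDING	SBI
lacune	SBI_FINDING	SBI
lacunes	SBI_FINDING	SBI
acute	SBI_MODIFIER_ACUTE	SBI
acute or subacute	SBI_MODIFIER_ACUTE	SBI
recent	SBI_MODIFIER_ACUTE	SBI
new	SBI_MODIFIER_ACUTE	SBI
remote	SBI_MODIFIER_CHRONIC	SBI
old	SBI_MODIFIER_CHRONIC	SBI
chronic	SBI_MODIFIER_CHRONIC	SBI
prior	SBI_MODIFIER_CHRONIC	SBI
chronic foci of	SBI_MODIFIER_CHRONIC	SBI
benign	SBI_MODIFIER_CHRONIC	SBI
stable small	SBI_MODIFIER_CHRONIC	SBI
stable	SBI_MODIFIER_CHRONIC	SBI
territorial	SBI_LOCATION	SBI
lacunar	SBI_LOCATION	SBI
cerebellar	SBI_LOCATION	SBI
cortical	SBI_LOCATION	SBI
frontal	SBI_LOCATION	SBI
caudate	SBI_LOCATION	SBI
right frontoparietal lobe	SBI_LOCATION	SBI
right frontal cortical	SBI_LOCATION	SBI
right frontal lobe	SBI_LOCATION	SBI
embolic	SBI_LOCATION	SBI
left basal ganglia lacunar	SBI_LOCATION	SBI
basal ganglia lacunar	SBI_LOCATION	SBI
left caudate and left putamen lacunar	SBI_LOCATION	SBI
leukoaraiosis	WMD_FINDING	WMD
white matter	WMD_FINDING	WMD
microvascular ischemic	WMD_FINDING	WMD
microvascular leukemic	WMD_FINDING	WMD
microvascular degenerative	WMD_FINDING	WMD
degenerative changes	WMD_EXCLUSION	WMD
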