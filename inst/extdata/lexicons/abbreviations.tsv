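tka	total knee arthroplasty
tha	total hip arthroplasty
appy	appendectomy
chole	cholecystectomy
phaco	phacoemulsification
cs	cesarean section
cabg	coronary artery bypass graft
orif	open reduction internal fixation
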