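repalcemnt	replacement
arthroplsty	arthroplasty
anestesia	anesthesia
cholecystecomy	cholecystectomy
appendecomy	appendectomy
artroscopy	arthroscopy
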