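species,magnification,precision,recall
wheat,400x,0.993,0.998
wheat,200x,0.898,0.917
wheat,100x,0.977,0.815
rice,400x,0.868,0.926
tomato,400x,0.836,0.913
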