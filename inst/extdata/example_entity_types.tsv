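ribavirin	drug
sofosbuvir	drug
interferon_alfa	drug
entecavir	drug
ns5b_polymerase	protein
ifnar1	protein
hepatitis_c	disease
hepatitis_b	disease
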