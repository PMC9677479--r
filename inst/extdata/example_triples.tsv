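ribavirin	treats	hepatitis_c
ribavirin	targets	ns5b_polymerase
sofosbuvir	targets	ns5b_polymerase
sofosbuvir	treats	hepatitis_c
ns5b_polymerase	associated_with	hepatitis_c
interferon_alfa	treats	hepatitis_b
interferon_alfa	targets	ifnar1
ifnar1	interacts_with	ns5b_polymerase
ifnar1	associated_with	hepatitis_b
entecavir	treats	hepatitis_b
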