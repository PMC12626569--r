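pt_code,pt_name
10051055,Deep vein thrombosis
10037377,Pulmonary embolism
10047249,Venous thrombosis
10014523,Embolism venous
10034272,Pelvic venous thrombosis
10057945,Venous thrombosis limb
10037437,Pulmonary thrombosis
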