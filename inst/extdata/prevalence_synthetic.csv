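"sex","complication","value"
"male","diabetes",0.0584940404503057
"male","hypertension",0.148336331368752
"male","chd",0.0278849523236831
"male","stroke",0.0131850812679712
"female","diabetes",0.049342593407433
"female","hypertension",0.128360077890021
"female","chd",0.0184436489416508
"female","stroke",0.01
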