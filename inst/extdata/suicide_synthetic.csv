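"sex","age","value"
"male",18,0.00018
"male",19,0.00018
"male",20,0.00018
"male",21,0.00018
"male",22,0.00018
"male",23,0.00018
"male",24,0.00018
"male",25,0.00018
"male",26,0.00018
"male",27,0.00018
"male",28,0.00018
"male",29,0.00018
"male",30,0.00018
"male",31,0.00018
"male",32,0.00018
"male",33,0.00018
"male",34,0.00018
"male",35,0.00018
"male",36,0.00018
"male",37,0.00018
"male",38,0.00018
"male",39,0.00018
"male",40,0.00018
"male",41,0.00018
"male",42,0.00018
"male",43,0.00018
"male",44,0.00018
"male",45,0.00018
"male",46,0.00018
"male",47,0.00018
"male",48,0.00018
"male",49,0.00018
"male",50,0.00018
"male",51,0.00018
"male",52,0.00018
"male",53,0.00018
"male",54,0.00018
"male",55,0.00018
"male",56,0.00018
"male",57,0.00018
"male",58,0.00018
"male",59,0.00018
"male",60,0.00018
"male",61,0.00018
"male",62,0.00018
"male",63,0.00018
"male",64,0.00018
"male",65,0.00018
"male",66,0.00018
"male",67,0.00018
"male",68,0.00018
"male",69,0.00018
"male",70,0.00018
"male",71,0.00018
"male",72,0.00018
"male",73,0.00018
"male",74,0.00018
"male",75,0.00018
"female",18,5.4e-05
"female",19,5.4e-05
"female",20,5.4e-05
"female",21,5.4e-05
"female",22,5.4e-05
"female",23,5.4e-05
"female",24,5.4e-05
"female",25,5.4e-05
"female",26,5.4e-05
"female",27,5.4e-05
"female",28,5.4e-05
"female",29,5.4e-05
"female",30,5.4e-05
"female",31,5.4e-05
"female",32,5.4e-05
"female",33,5.4e-05
"female",34,5.4e-05
"female",35,5.4e-05
"female",36,5.4e-05
"female",37,5.4e-05
"female",38,5.4e-05
"female",39,5.4e-05
"female",40,5.4e-05
"female",41,5.4e-05
"female",42,5.4e-05
"female",43,5.4e-05
"female",44,5.4e-05
"female",45,5.4e-05
"female",46,5.4e-05
"female",47,5.4e-05
"female",48,5.4e-05
"female",49,5.4e-05
"female",50,5.4e-05
"female",51,5.4e-05
"female",52,5.4e-05
"female",53,5.4e-05
"female",54,5.4e-05
"female",55,5.4e-05
"female",56,5.4e-05
"female",57,5.4e-05
"female",58,5.4e-05
"female",59,5.4e-05
"female",60,5.4e-05
"female",61,5.4e-05
"female",62,5.4e-05
"female",63,5.4e-05
"female",64,5.4e-05
"female",65,5.4e-05
"female",66,5.4e-05
"female",67,5.4e-05
"female",68,5.4e-05
"female",69,5.4e-05
"female",70,5.4e-05
"female",71,5.4e-05
"female",72,5.4e-05
"female",73,5.4e-05
"female",74,5.4e-05
"female",75,5.4e-05
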