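"sex","age","value"
"male",18,0.000252622601363828
"male",19,0.000276409865633376
"male",20,0.000302436630039926
"male",21,0.000330913670041899
"male",22,0.000362071585515156
"male",23,0.000396162662733457
"male",24,0.000433462910719107
"male",25,0.000474274288194576
"male",26,0.000518927138850933
"male",27,0.000567782854275833
"male",28,0.000621236785650625
"male",29,0.000679721427246927
"male",30,0.000743709896845357
"male",31,0.000813719740472951
"male",32,0.000890317091320925
"male",33,0.000974121215386647
"male",34,0.00106580947928669
"male",35,0.00116612277883577
"male",36,0.00127587147039165
"male",37,0.00139594185065051
"male",38,0.00152730323454808
"male",39,0.00167101568521322
"male",40,0.00182823845452806
"male",41,0.00200023919780823
"male",42,0.00218840403142817
"male",43,0.00239424850790049
"male",44,0.00261942958897998
"male",45,0.00286575870381356
"male",46,0.00313521598598676
"male",47,0.00342996579053323
"male",48,0.00375237359954794
"male",49,0.00410502443295668
"male",50,0.00449074288920748
"male",51,0.00491261494909512
"male",52,0.0053740116845411
"male",53,0.00587861502281295
"male",54,0.00643044572524454
"male",55,0.00703389374784025
"male",56,0.00769375115896986
"male",57,0.00841524779642755
"male",58,0.00920408985206378
"male",59,0.0100665015765814
"male",60,0.0110092702993784
"male",61,0.0120397949578668
"male",62,0.0131661383267105
"male",63,0.0143970831289483
"male",64,0.0157421921968541
"male",65,0.0172118728292598
"male",66,0.0188174454622876
"male",67,0.0205712167300797
"male",68,0.02248655693887
"male",69,0.0245779819089371
"male",70,0.0268612390514801
"male",71,0.0293533974376061
"male",72,0.0320729414802333
"male",73,0.0350398676819574
"male",74,0.0382757836973543
"male",75,0.0418040087106114
"female",18,0.000176842522597087
"female",19,0.000193494929157878
"female",20,0.000211715246417943
"female",21,0.000231651068583361
"female",22,0.000253463877083249
"female",23,0.000277330345952786
"female",24,0.000303443769669953
"female",25,0.000332015624882054
"female",26,0.000363277278520147
"female",27,0.000397481855947901
"female",28,0.000434906284058401
"female",29,0.000475853525595427
"female",30,0.000520655022479333
"female",31,0.000569673367538437
"female",32,0.000623305225826432
"female",33,0.000681984528627333
"female",34,0.000746185965355473
"female",35,0.000816428800829883
"female",36,0.000893281047884553
"female",37,0.000977364027957561
"female",38,0.00106935735522062
"female",39,0.00117000438296411
"female",40,0.0012801181543679
"female",41,0.00140058790348485
"female",42,0.00153238615624551
"female",43,0.0016765764855935
"female",44,0.00183432197948463
"female",45,0.00200689448545099
"female",46,0.00219568470076048
"female",47,0.0024022131828958
"female",48,0.00262814236115771
"female",49,0.00287528963665507
"female",50,0.00314564166479758
"female",51,0.00344136992162603
"female",52,0.00376484766291063
"female",53,0.00411866839286756
"female",54,0.00450566596756652
"female",55,0.00492893646655834
"female",56,0.00539186197486219
"female",57,0.00589813642611825
"female",58,0.00645179366627968
"female",59,0.00705723790552459
"female",60,0.00771927673387485
"female",61,0.00844315688303343
"female",62,0.00923460292284373
"female",63,0.0100998590850873
"female",64,0.0110457344095375
"female",65,0.0120796514066224
"female",66,0.0132096984269093
"female",67,0.0144446859189672
"female",68,0.0157942067428097
"female",69,0.0172687006847101
"female",70,0.0188795232890455
"female",71,0.0206390190820357
"female",72,0.0225605992084715
"female",73,0.024658823433097
"female",74,0.026949486370046
"female",75,0.029449707692986
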