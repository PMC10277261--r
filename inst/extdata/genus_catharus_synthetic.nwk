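(((Catharus_occidentalis:1.548106599,Catharus_guttatus:1.548106599):3.087874595,(Catharus_dryas:0.5703906774,(Catharus_mexicanus:0.2484718761,Catharus_gracilirostris:0.2484718761):0.3219188013):4.065590517):0.09401880562,(Catharus_aurantiirostris:3.567560914,((((Catharus_bicknelli:0.9664680422,Catharus_fuscater:0.9664680422):1.032398259,(Catharus_ustulatus:0.4533519804,Catharus_fuscescens:0.4533519804):1.545514321):0.3490568834,Catharus_frantzii:2.347923185):1.02949517,Catharus_minimus:3.377418355):0.1901425595):1.162439086);
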