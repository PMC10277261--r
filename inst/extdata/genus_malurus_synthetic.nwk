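((((((Malurus_lamberti:4.029862325,Malurus_amabilis:4.029862325):0.103092686,(Malurus_grayi:1.706622838,Malurus_cyaneus:1.706622838):2.426332173):2.47744006,(Malurus_elegans:3.615058922,Malurus_melanocephalus:3.615058922):2.995336149):1.490405745,Malurus_pulcherrimus:8.100800816):0.6113698689,Malurus_coronatus:8.712170685):0.2878293154,((Malurus_leucopterus:1.186607182,Malurus_splendens:1.186607182):0.8112159786,Malurus_alboscapulatus:1.997823161):7.002176839);
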