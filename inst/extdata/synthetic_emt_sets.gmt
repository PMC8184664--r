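epithelial_markers	illustrative synthetic epithelial marker set	Cdh1	Epcam	Cldn3	Cldn4	Cldn7	Ocln	Dsp	Krt8	Krt18	Krt19	Tjp1	Esrp1	Grhl2	Cdh17	Muc1
mesenchymal_markers	illustrative synthetic mesenchymal/EMT marker set	Vim	Cdh2	Fn1	Snai1	Snai2	Twist1	Twist2	Zeb1	Zeb2	Acta2	S100a4	Mmp2	Mmp9	Foxc2	Prrx1
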