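>SYNF1
MKTLLVAAGLLACSQAWNVNTTESPGKLQVLQ
>SYNF2
MKTLLVAAGLLACSQAWNVNTTESPGKLRVLQ
>SYNF3
MKTLLVAGGLLTCSQAWNVDTTKSPGKLRVLQ
>SYNF4
MRSLIVGGGILTCAQGWHVDSTKAPGRLRILE
>SYNOUT
GGGGGPPPPPWWWWWHHHHHKKKKKEEEEEDD
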