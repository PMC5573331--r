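>tasiARF_D7 canonical Arabidopsis TAS3a 5'D7(+) tasiARF
UUCUUGACCUUGUAAGACCCC
>tasiARF_D8 canonical Arabidopsis TAS3a 5'D8(+) tasiARF
UUCUUGACCUUGUAAGGCCUU
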