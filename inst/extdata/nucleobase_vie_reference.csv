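molecule,class,base,vie_gas_calcd,vie_gas_exp,vie_aq_calcd
guanine,base,guanine,7.92,8.24,
adenine,base,adenine,8.21,8.44,
thymine,base,thymine,8.97,9.14,
cytosine,base,cytosine,8.71,8.94,
guanosine,nucleoside,guanine,,,7.66
adenosine,nucleoside,adenine,,,7.94
thymidine,nucleoside,thymine,,,8.29
cytidine,nucleoside,cytosine,,,8.26
dGMP,nucleotide,guanine,,,7.57
dAMP,nucleotide,adenine,,,7.86
dTMP,nucleotide,thymine,,,8.22
dCMP,nucleotide,cytosine,,,8.17
GG_5p,dinucleotide,guanine,,,7.59
GG_3p,dinucleotide,guanine,,,7.56
AA_5p,dinucleotide,adenine,,,7.85
AA_3p,dinucleotide,adenine,,,7.79
TT_5p,dinucleotide,thymine,,,8.27
TT_3p,dinucleotide,thymine,,,8.28
CC_5p,dinucleotide,cytosine,,,8.23
CC_3p,dinucleotide,cytosine,,,8.20
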