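molecule,vred_pmm_V
guanosine,1.05
adenosine,1.26
thymidine,1.73
cytidine,1.87
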