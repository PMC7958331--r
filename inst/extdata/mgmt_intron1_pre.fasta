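>PRE-1 p53 response element, MGMT intron-1 (reverse strand)
AGGCAAGCCCACACCCAGGCTAGCAC
>PRE-2 p53 response element, MGMT intron-1 (reverse strand)
AAGCATGCAAAAAGCAAAAACATGTAT
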