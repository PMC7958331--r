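>hsa-miR-574-5p
UGUGUGUGUGUGUGUGUGUGUGU
>hsa-miR-4297
UGCCUUCCUGUCUGUG
>hsa-miR-4645-3p
UAGUUCUUGCCUGG
>hsa-miR-942-5p
ACAUGGCCAAAACAGAG
>hsa-miR-4726-3p
AGGUUCCCUCUGGCCGC
>hsa-miR-6862-5p
GCAUGCUGGGAGAGACU
>hsa-miR-127-3p
UCGGAUCCGUCUGAGCUUGGCU
>hsa-miR-370-3p
GCCUGCUGGGGUGGAACCUGGU
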