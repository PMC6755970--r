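>hsa-miR-346 MIMAT0000773
UGUCUGCCCGCAUGCCUGCCUCU
>hsa-miR-361-3p MIMAT0004682
UCCCCCAGGUGUGAUUCUGAUUU
>hsa-miR-197-3p MIMAT0000227
UUCACCACCUUCUCCACCCAGC
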