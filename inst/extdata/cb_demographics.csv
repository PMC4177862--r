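subject_id,group,sex,age
cb01,CB,F,49
cb02,CB,M,41
cb03,CB,M,39
cb04,CB,M,58
cb05,CB,M,38
cb06,CB,F,31
cb07,CB,M,20
cb08,CB,M,23
cb09,CB,M,27
cb10,CB,F,27
cb11,CB,F,42
cb12,CB,M,60
cb13,CB,F,31
cb14,CB,F,23
cb15,CB,M,35
cb16,CB,M,57
cb17,CB,M,58
cb18,CB,F,19
cb19,CB,F,63
cb20,CB,F,26
cb21,CB,M,56
cb22,CB,F,21
cb23,CB,M,21
cb24,CB,F,41
cb25,CB,M,19
cb26,CB,M,23
cb27,CB,F,27
cb28,CB,M,23
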