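id,group,chronological_age,mental_age,macs,gmfcs,fma_total
C-01,control,4,4,,,65
C-02,control,4,4,,,64
C-03,control,5,5,,,65
C-04,control,5,5,,,66
C-05,control,5,5,,,66
C-06,control,6,6,,,65
C-07,control,7,7,,,64
C-08,control,8,8,,,66
C-09,control,8,8,,,66
C-10,control,8,8,,,66
C-11,control,9,9,,,63
C-12,control,9,9,,,63
C-13,control,9,9,,,63
C-14,control,9,9,,,63
C-15,control,11,11,,,66
C-16,control,11,11,,,66
C-17,control,11,11,,,66
C-18,control,12,12,,,66
S-01,study,4,-,I,II,57
S-02,study,5,4,II,II,60
S-03,study,5,4,I,II,54
S-04,study,6,4,II,II,50
S-05,study,6,6,I,I,63
S-06,study,8,6,I,I,65
S-07,study,8,5,II,II,39
S-08,study,8,7,II,I,64
S-09,study,9,5,II,II,52
S-10,study,9,-,I,II,53
S-11,study,9,7,I,II,57
S-12,study,9,5,II,II,42
S-13,study,9,8,I,I,65
S-14,study,9,4,I,I,65
S-15,study,10,5,I,I,62
S-16,study,11,7,I,II,66
S-17,study,12,8,II,I,31
S-18,study,12,9,II,I,58
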