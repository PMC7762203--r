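# Core-gene name patterns (case-insensitive regular expressions).
# Core-gene membership is configuration, not computation: edit or replace
# this table to match the naming of your annotation source.
polh|granulin
pif-?0|p74
pif-?1
pif-?2
pif-?3
pif-?4
pif-?5|odv-e56
pif-?6
pif-?7|vp91
pif-?8
lef-?1
lef-?2
lef-?4
lef-?5
lef-?8
lef-?9
p47
dnapol
helicase|p143
alk-?exo
vlf-?1
vp39
vp1054
gp41
p6\.9
38k
p33
p18
p40
p48
p49
odv-e18
odv-e25
odv-ec27
odv-e66
ac53
ac78
ac81
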