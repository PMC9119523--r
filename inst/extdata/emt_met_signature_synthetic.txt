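SNAI1
SNAI2
GRHL1
GRHL2
GRHL3
ZEB1
ZEB2
TWIST1
TWIST2
CDH1
CDH2
VIM
FN1
CLDN4
CLDN7
ESRP1
ESRP2
CRB3
OVOL1
OVOL2
EMT-SYN-001
EMT-SYN-002
EMT-SYN-003
EMT-SYN-004
EMT-SYN-005
EMT-SYN-006
EMT-SYN-007
EMT-SYN-008
EMT-SYN-009
EMT-SYN-010
EMT-SYN-011
EMT-SYN-012
EMT-SYN-013
EMT-SYN-014
EMT-SYN-015
EMT-SYN-016
EMT-SYN-017
EMT-SYN-018
EMT-SYN-019
EMT-SYN-020
EMT-SYN-021
EMT-SYN-022
EMT-SYN-023
EMT-SYN-024
EMT-SYN-025
EMT-SYN-026
EMT-SYN-027
EMT-SYN-028
EMT-SYN-029
EMT-SYN-030
EMT-SYN-031
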