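# Mean centroid-to-centroid distance (mm) between adjacent vertebrae,
# literature-plausible values for an adult spine. Editable configuration:
# the loss, the phantom generator and the tests all read the same table.
C1-C2: 17
C2-C3: 17
C3-C4: 18
C4-C5: 18
C5-C6: 19
C6-C7: 20
C7-T1: 20
T1-T2: 21
T2-T3: 21
T3-T4: 22
T4-T5: 22
T5-T6: 23
T6-T7: 24
T7-T8: 24
T8-T9: 25
T9-T10: 25
T10-T11: 26
T11-T12: 27
T12-L1: 28
L1-L2: 30
L2-L3: 32
L3-L4: 33
L4-L5: 34
L5-S1: 33
S1-S2: 30
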