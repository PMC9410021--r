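# Average vertebral-body extent in mm along (sagittal, row, column) axes,
# used to inflate sparse centroids into dense box labels. Column extents are
# kept below the adjacent reference distances so dense labels of neighbouring
# vertebrae do not touch (the inter-vertebral gap).
C1: [26, 26, 12]
C2: [26, 26, 12]
C3: [26, 26, 12]
C4: [26, 26, 12]
C5: [26, 26, 12]
C6: [26, 26, 12]
C7: [26, 26, 12]
T1: [30, 30, 16]
T2: [30, 30, 16]
T3: [30, 30, 16]
T4: [30, 30, 16]
T5: [32, 32, 18]
T6: [32, 32, 18]
T7: [32, 32, 18]
T8: [32, 32, 18]
T9: [34, 34, 20]
T10: [34, 34, 20]
T11: [34, 34, 20]
T12: [34, 34, 20]
L1: [40, 40, 24]
L2: [40, 40, 24]
L3: [40, 40, 24]
L4: [40, 40, 24]
L5: [40, 40, 24]
S1: [42, 42, 24]
S2: [38, 38, 22]
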