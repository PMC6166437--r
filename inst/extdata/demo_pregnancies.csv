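id,outcome,end_cm,is_current
w1,abortion,1322,FALSE
w2,abortion,1290,FALSE
w3,live_birth_vaginal,1347,FALSE
w4,miscarriage,1313,FALSE
w4,live_birth_cesarean,1361,FALSE
w6,live_birth_vaginal,1271,FALSE
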