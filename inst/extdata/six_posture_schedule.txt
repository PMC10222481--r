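# Six-posture validation protocol: initialization hold, then each incorrect
# posture followed by a return to the correct one.
symmetric 10
lean_fwd_left 20
symmetric 20
lean_fwd_right 20
symmetric 20
lean_back_left 20
symmetric 20
lean_back_right 20
symmetric 20
cross_left_leg 20
symmetric 20
cross_right_leg 20
symmetric 20
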