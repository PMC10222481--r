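# Read-out chain constants of the reference four-sensor seat cushion
cal_slope = 0.950
cal_intercept = 9.848
supply_voltage = 3.3
ref_conductance = 100
adc_bits = 10
accuracy_fraction = 0.025
sampling_interval = 0.5
queue_length = 5
min_seated_force = 10
uncertainty_propagation = sum
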