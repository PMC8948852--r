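side,movement,reference_deg,measured_mean_deg
right,shoulder_abduction,30,30.549
right,shoulder_abduction,60,59.994
right,shoulder_abduction,90,90.425
right,shoulder_abduction,120,120.546
right,elbow_flexion,45,45.664
right,elbow_flexion,90,90.624
right,elbow_flexion,135,135.449
right,elbow_flexion,180,180.548
left,shoulder_abduction,30,30.257
left,shoulder_abduction,60,60.59
left,shoulder_abduction,90,90.514
left,shoulder_abduction,120,120.876
left,elbow_flexion,45,45.54
left,elbow_flexion,90,90.504
left,elbow_flexion,135,135.511
left,elbow_flexion,180,180.603
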