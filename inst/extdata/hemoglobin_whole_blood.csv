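# Whole-blood absorption coefficient, 450-700 nm (mm^-1).
# Synthetic approximate compilation of the standard literature oxy/deoxy-
# hemoglobin molar extinction tabulation, converted to whole blood at
# 150 g/L hemoglobin (MW 64500 g/mol): mua = ln(10) * eps * C / 10.
# Linear interpolation between grid points; no extrapolation.
wavelength_nm,mua_oxy_mm,mua_deoxy_mm
450,33.637,55.3113
460,23.8184,38.8912
470,17.7829,25.6685
480,14.2594,16.5406
490,12.6824,12.5239
500,11.2088,11.1713
510,10.7284,13.8011
520,12.9598,16.9154
530,21.3958,21.1179
540,28.5071,24.9493
550,24.1354,28.3229
560,17.4638,28.6013
570,24.1595,27.2797
580,26.8299,24.6286
590,7.8593,20.4673
600,1.7136,7.8593
610,0.8064,3.486
620,0.5044,2.6405
630,0.3266,2.3272
640,0.2367,2.0081
650,0.1971,1.728
660,0.1708,1.4972
670,0.1574,1.2889
680,0.1483,1.0988
690,0.1478,0.9607
700,0.1553,0.89
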