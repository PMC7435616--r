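subject_id,behavior,test_min,criterion_min
S001,sitting,221.97,228.45
S002,sitting,76.99,81.06
S003,sitting,171.27,193.32
S004,sitting,192.51,172.69
S005,sitting,118.15,119.1
S006,sitting,26.29,0
S007,sitting,136.49,112.79
S008,sitting,85.74,86.55
S009,sitting,198.75,190.96
S010,sitting,160.48,136.86
S011,sitting,133.49,142.9
S012,sitting,114,113.23
S013,sitting,154.71,160.11
S014,sitting,162.92,159.7
S015,sitting,1.01,0
S016,sitting,319.96,304.56
S017,sitting,244.31,237.27
S018,sitting,185.81,200.54
S019,sitting,113.18,106.39
S020,sitting,230.28,244.03
S001,standing,26.86,33.62
S002,standing,100.89,103.49
S003,standing,24.39,31.93
S004,standing,77.69,86.47
S005,standing,17.04,45.3
S006,standing,118.06,126.59
S007,standing,71.95,101.1
S008,standing,71.58,60.87
S009,standing,85.86,104.26
S010,standing,87.95,90.8
S011,standing,35.33,33.17
S012,standing,63.18,67.96
S013,standing,55.14,41.8
S014,standing,75.34,91.62
S015,standing,53.26,52.12
S016,standing,49,67.05
S017,standing,54.6,30.77
S018,standing,45.14,40.71
S019,standing,70.75,80.24
S020,standing,45.08,39.33
S001,stepping,23.11,11.87
S002,stepping,36.89,39.84
S003,stepping,11.13,11.87
S004,stepping,0,7.65
S005,stepping,32.84,23.42
S006,stepping,38.73,32.92
S007,stepping,12.05,23.88
S008,stepping,29.46,16.02
S009,stepping,27.79,36.35
S010,stepping,41.77,49.35
S011,stepping,0,3.44
S012,stepping,30.72,39.47
S013,stepping,17.28,19.01
S014,stepping,39.87,34.3
S015,stepping,0.09,4.84
S016,stepping,20.76,21.26
S017,stepping,12.75,13.93
S018,stepping,29.72,18.85
S019,stepping,32.83,12.69
S020,stepping,20.16,27.88
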