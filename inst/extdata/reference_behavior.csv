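id,rt_train1_ms,bt_train1,rt_train2_ms,bt_train2,rt_test_simple_ms,bt_test_simple,rt_test_complex_ms,bt_test_complex,ct_test_complex
1,356.4,1,387.7,2,370.4,1,357.9,0,0
2,377.7,0,427.0,2,452.6,3,436.5,8,9
3,386.5,2,371.4,0,384.4,0,454,2,6
4,295.1,0,303.7,0,305.5,0,359.8,2,6
5,323.9,0,336.9,0,342.3,0,462.2,1,1
6,355.0,0,386.3,9,368.5,3,480.4,5,0
7,348.4,0,347.1,0,337.8,0,424.1,4,9
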