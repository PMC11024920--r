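tag_id,site_id,sex,age,immigrant,strength,prior_detections,novel_count,familiar_count
B01,S1,M,juvenile,TRUE,2.1287,194,34,22
B02,S1,M,adult,FALSE,1.2936,193,43,23
B03,S1,F,juvenile,TRUE,2.2947,210,32,23
B04,S1,F,juvenile,TRUE,1.6577,202,33,29
B05,S1,F,adult,TRUE,1.3636,189,35,27
B06,S1,M,adult,FALSE,1.5885,188,33,36
B07,S1,M,juvenile,TRUE,1.3168,206,32,30
B08,S1,M,juvenile,FALSE,0.4483,197,26,30
B09,S1,M,adult,TRUE,1.2163,205,47,35
B10,S1,M,adult,TRUE,1.475,208,35,25
B11,S1,F,juvenile,TRUE,2.1784,222,37,17
B12,S1,M,juvenile,TRUE,0.6145,193,26,34
B13,S1,M,juvenile,FALSE,1.4063,198,25,23
B14,S1,F,adult,TRUE,1.3707,205,29,33
B15,S1,M,juvenile,TRUE,0.6417,189,20,29
B16,S1,M,adult,TRUE,0.9765,218,37,28
B17,S1,M,juvenile,FALSE,1.96,193,39,32
B18,S1,F,juvenile,TRUE,1.1042,204,30,35
B19,S1,M,juvenile,FALSE,1.5387,199,33,37
B20,S1,F,adult,FALSE,0.6999,188,38,34
B21,S2,M,juvenile,TRUE,1.365,219,11,38
B22,S2,F,juvenile,TRUE,1.4404,201,22,57
B23,S2,F,adult,TRUE,1.9327,209,17,44
B24,S2,M,juvenile,FALSE,1.6517,190,14,56
B25,S2,M,adult,FALSE,0.9624,205,16,46
B26,S2,F,juvenile,TRUE,1.4874,192,13,49
B27,S2,F,juvenile,FALSE,1.7134,201,20,51
B28,S2,F,juvenile,FALSE,1.5481,190,16,46
B29,S2,F,adult,TRUE,0.9763,211,18,52
B30,S2,M,juvenile,TRUE,1.702,182,28,41
B31,S2,F,juvenile,TRUE,1.4765,195,18,55
B32,S2,F,adult,TRUE,1.2256,224,16,34
B33,S2,M,juvenile,FALSE,1.9111,194,16,57
B34,S2,F,adult,FALSE,1.4684,180,18,46
B35,S2,F,juvenile,FALSE,1.6269,195,18,39
B36,S2,F,adult,FALSE,2.4311,188,22,49
B37,S2,M,juvenile,FALSE,1.4104,186,10,42
B38,S2,F,adult,FALSE,0.672,201,16,50
B39,S2,M,adult,TRUE,0.725,189,11,47
B40,S2,F,adult,FALSE,2.0425,199,24,52
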