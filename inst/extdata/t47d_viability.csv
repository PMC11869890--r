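arm,replicate_index,viability
Bleomycin,1,0.8651
Bleomycin,2,0.8308
Bleomycin,3,1.1593
Bleomycin,4,0.8374
Bleomycin,5,0.8043
Bleomycin,6,0.7598
Bleomycin,7,0.6332
Bleomycin,8,0.8417
Bortezomib,1,0.7793
Bortezomib,2,0.7798
Bortezomib,3,0.8857
Bortezomib,4,0.8288
Bortezomib,5,0.8641
Bortezomib,6,0.7557
Bortezomib,7,0.5992
Bortezomib,8,0.6336
Combination1,1,0.6603
Combination1,2,0.7207
Combination1,3,0.7435
Combination1,4,0.7579
Combination1,5,0.5590
Combination1,6,0.6598
Combination1,7,0.5037
Combination1,8,0.6431
Combination2,1,0.6315
Combination2,2,0.5755
Combination2,3,0.6951
Combination2,4,0.7582
Combination2,5,0.6176
Combination2,6,0.6719
Combination2,7,0.4989
Combination2,8,0.6852
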