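# Body-frame semi-axes and segment heights (cm): head ellipse (A_H, B_H) of
# height C_H stacked on a trunk ellipse (A_T, B_T) of height C_T, with legs
# of length C_L below the trunk.
phantom,A_H,B_H,C_H,A_T,B_T,C_T,C_L
ORNL,8.0,10.0,28.6,20.0,10.0,70.0,80.0
TRM,7.8,9.7,27.0,18.0,9.7,64.7,77.0
TRW,7.6,9.4,25.2,16.9,9.4,58.1,72.9
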