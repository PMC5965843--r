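region_id,class,vertex,phi,psi
F_alpha,favored,1,-160,-75
F_alpha,favored,2,-160,-5
F_alpha,favored,3,-45,-5
F_alpha,favored,4,-45,-75
F_beta,favored,1,-170,90
F_beta,favored,2,-170,175
F_beta,favored,3,-50,175
F_beta,favored,4,-50,90
A_alpha_broad,allowed,1,-180,-110
A_alpha_broad,allowed,2,-180,60
A_alpha_broad,allowed,3,-20,60
A_alpha_broad,allowed,4,-20,-110
A_beta_broad,allowed,1,-180,60
A_beta_broad,allowed,2,-180,180
A_beta_broad,allowed,3,-20,180
A_beta_broad,allowed,4,-20,60
A_beta_wrap,allowed,1,-180,-180
A_beta_wrap,allowed,2,-180,-150
A_beta_wrap,allowed,3,-20,-150
A_beta_wrap,allowed,4,-20,-180
A_alpha_L,allowed,1,20,-20
A_alpha_L,allowed,2,20,90
A_alpha_L,allowed,3,100,90
A_alpha_L,allowed,4,100,-20
G_plus_hi,glycine,1,45,120
G_plus_hi,glycine,2,45,180
G_plus_hi,glycine,3,180,180
G_plus_hi,glycine,4,180,120
G_plus_lo,glycine,1,45,-180
G_plus_lo,glycine,2,45,-60
G_plus_lo,glycine,3,180,-60
G_plus_lo,glycine,4,180,-180
G_plus_mid,glycine,1,100,-60
G_plus_mid,glycine,2,100,120
G_plus_mid,glycine,3,180,120
G_plus_mid,glycine,4,180,-60
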