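eye_id,group,gender,age_years,bcva_logmar,small_drusen,large_drusen,drusenoid_ped,atrophy,rpd,cmt_um,ct_um
neo1,neovascular,female,72,0.1,1,1,1,0,1,252,257
neo2,neovascular,female,78,0.0,0,0,1,0,0,211,139
neo3,neovascular,male,80,0.2,0,0,1,0,0,338,136
neo4,neovascular,male,82,0.1,0,0,0,0,0,249,289
neo5,neovascular,female,91,0.3,1,1,1,0,1,264,243
neo6,neovascular,female,72,0.1,1,1,1,0,1,244,382
neo7,neovascular,female,89,0.2,0,0,1,0,1,239,268
neo8,neovascular,female,88,0.0,0,1,1,0,0,204,102
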