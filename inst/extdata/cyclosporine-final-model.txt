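# Final population pharmacokinetic model for cyclosporine (whole blood, TDM)
# Typical values: apparent parameters (oral dosing); variances on the log scale.
tlag_pop = 0.512
ka_pop = 0.523
cl_pop = 30.3
q_pop = 17.0
v1_pop = 17.9
v2_pop = 400
beta_clcrea = -0.204
clcrea_ref = 98.62
omega2_cl = 0.147043195682027
omega2_q = 0.249219791615985
gamma2_cl = 0.134880482193818
gamma2_tlag = 0.256718356280665
gamma2_ka = 0.244259825202683
rho_ka_cl = -0.551
sigma_prop = 0.228
sigma_add = 7.52
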