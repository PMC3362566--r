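# Default NPZD biological parameters (rates per day)
k_w          = 0.04     # light attenuation in seawater, m^-1
k_chla       = 0.024    # light attenuation by chlorophyll, m^-1 (mg Chla m^-3)^-1
alpha        = 1.0      # initial slope of the P-I curve, mg C (mg Chla W m^-2 d)^-1
c2n          = 6.625    # C:N ratio for phytoplankton, mol C (mol N)^-1
theta_max    = 0.03     # maximum cellular chlorophyll:C ratio, mg Chla (mg C)^-1
K_N          = 1.5      # half-saturation for phytoplankton NO3 uptake, mmol N m^-3
K_P          = 1.0      # zooplankton half-saturation constant for ingestion, mmol N m^-3
g_max        = 0.9      # maximum zooplankton growth rate, d^-1
beta         = 0.75     # zooplankton assimilation coefficient
m_P          = 0.03     # phytoplankton mortality (to detritus) rate, d^-1
m_Z          = 0.1      # zooplankton mortality (to detritus) rate, d^-1
e_Z          = 0.1      # zooplankton specific excretion rate, d^-1
r_D          = 0.05     # detrital mineralisation to NO3 rate, d^-1
w_P          = 0.5      # sinking velocity for phytoplankton, m d^-1
w_D          = 5        # sinking velocity for detritus, m d^-1
par_fraction = 0.43     # surface PAR as a fraction of incident shortwave
mu0          = 0.59     # maximum growth at 0 C, d^-1 (Eppley)
a_T          = 1.066    # Eppley temperature base, per degree C
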