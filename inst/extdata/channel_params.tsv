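channel	parameter	value	unit	description
it_tc	m_vhalf	-59	mV	activation half-voltage
it_tc	m_slope	6.2	mV	activation slope
it_tc	h_vhalf	-83	mV	inactivation half-voltage
it_tc	h_slope	-4	mV	inactivation slope
it_tc	phi_m	6.96	1	activation temperature factor
it_tc	phi_h	3.74	1	inactivation temperature factor
it_re	m_vhalf	-52	mV	activation half-voltage
it_re	m_slope	7.4	mV	activation slope
it_re	h_vhalf	-80	mV	inactivation half-voltage
it_re	h_slope	-5	mV	inactivation slope
ih	s_vhalf	-75	mV	voltage gate half-activation
ih	s_slope	-5.5	mV	voltage gate slope
ih	k1	2.5e+07	mM^-4 ms^-1	Ca binding rate (on Ca^4)
ih	k2	4e-04	ms^-1	Ca unbinding rate
ih	k3	0.1	ms^-1	open-state locking rate (times P1)
ih	k4	0.001	ms^-1	unlocking rate
ih	g_inc	2	1	locked-open conductance gain
na_k	vtraub	-63	mV	rate-function voltage shift
km	q	2.95	1	rate temperature factor
km	vhalf	-30	mV	rate singular point (limit value)
kca	k_f	5	mM^-1 ms^-1	Ca-dependent forward rate
kca	beta	0.01	ms^-1	backward rate
nap	m_vhalf	-42	mV	activation half-voltage
nap	m_slope	5	mV	activation slope
hva	q	2.95	1	rate temperature factor
ampa	alpha	1.1	mM^-1 ms^-1	binding rate
ampa	beta	0.19	ms^-1	unbinding rate
nmda	alpha	0.072	mM^-1 ms^-1	binding rate
nmda	beta	0.0066	ms^-1	unbinding rate
nmda	mg_mm	1	mM	extracellular magnesium
gabaa	alpha	5	mM^-1 ms^-1	binding rate
gabaa	beta	0.18	ms^-1	unbinding rate
gabab	K1	0.52	mM^-1 ms^-1	receptor activation
gabab	K2	0.0013	ms^-1	receptor deactivation
gabab	K3	0.098	ms^-1	G-protein production
gabab	K4	0.033	ms^-1	G-protein decay
gabab	Kd	100	1	half-activation of G^4
pulse	amplitude	0.5	mM	transmitter pulse amplitude
pulse	duration	0.3	ms	transmitter pulse duration
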