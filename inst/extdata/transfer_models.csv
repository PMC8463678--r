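# Published single-proxy transfer functions for the Taimyr larch isotope reconstructions
# prediction = intercept + slope * proxy + offset
name,proxy,target,slope,intercept,offset
july_precip_d13c,d13C,July precipitation (mm),-16.723,-357.791,0.15
ao_may_d18o,d18O,May Arctic Oscillation index,0.320,-7.075,0.15
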