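name,file,quantity,material_or_phantom,units,interpolation,geometry,source
mu_rho_aluminum,mu_rho_aluminum.csv,mass attenuation coefficient,aluminum,cm2/g,loglog,narrow beam,NIST standard compilation (Hubbell & Seltzer type)
mu_en_rho_aluminum,mu_en_rho_aluminum.csv,mass energy-absorption coefficient,aluminum,cm2/g,loglog,narrow beam,NIST standard compilation (Hubbell & Seltzer type)
mu_rho_air,mu_rho_air.csv,mass attenuation coefficient,air (dry near sea level),cm2/g,loglog,narrow beam,NIST standard compilation (Hubbell & Seltzer type)
mu_en_rho_air,mu_en_rho_air.csv,mass energy-absorption coefficient,air (dry near sea level),cm2/g,loglog,narrow beam,NIST standard compilation (Hubbell & Seltzer type)
mu_rho_tungsten,mu_rho_tungsten.csv,mass attenuation coefficient,tungsten,cm2/g,loglog,narrow beam,NIST-type compilation; L-edge region (10-12.5 keV) approximated
hp3_ka,hp3_ka_cylinder_0deg_synthetic.csv,Hp(3) per air kerma conversion coefficient,ICRU cylinder head phantom,Sv/Gy,linear,photons at 0 degrees incidence,synthetic Behrens-type compilation calibrated to K(56.47 keV)=1.650
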