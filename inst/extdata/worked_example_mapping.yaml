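columns:
  person_id: id
  wears_correction: glasses
  ucva_left: va_unc_l
  ucva_right: va_unc_r
  cva_left: va_cor_l
  cva_right: va_cor_r
  pinhole_left: va_ph_l
  pinhole_right: va_ph_r
  age_years: age
  sex: sex
acuity_dialect: metric_6
strata:
  residence: residence
correction_definition: spectacles or contact lenses
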