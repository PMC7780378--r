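doctor
patient
father
mother
hospital
medicine
tablet
dose
levodopa
year
month
week
today
recently
started
taking
helps
little
much
often
sometimes
condition
disease
advice
thanks
please
question
visit
clinic
therapy
exercise
diet
water
family
because
really
getting
better
worse
still
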