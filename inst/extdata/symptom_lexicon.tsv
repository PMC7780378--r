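term	canonical_symptom	category	subcategory	nocturnal_only
tremor	tremor	motor	tremor	FALSE
tremors	tremor	motor	tremor	FALSE
shaking	tremor	motor	tremor	FALSE
trembling	tremor	motor	tremor	FALSE
stiffness	stiffness	motor	rigidity	FALSE
rigidity	stiffness	motor	rigidity	FALSE
stiff	stiffness	motor	rigidity	FALSE
turning over	difficulty_turning_over	motor	rigidity	FALSE
difficulty turning over	difficulty_turning_over	motor	rigidity	FALSE
immobility	immobility	motor	rigidity	FALSE
frozen	immobility	motor	rigidity	FALSE
difficulty walking	difficulty_walking	motor	bradykinesia	FALSE
slow movement	difficulty_walking	motor	bradykinesia	FALSE
shuffling	difficulty_walking	motor	bradykinesia	FALSE
bradykinesia	difficulty_walking	motor	bradykinesia	FALSE
reduced facial expression	reduced_facial_expression	motor	bradykinesia	FALSE
masked face	reduced_facial_expression	motor	bradykinesia	FALSE
unclear enunciation	unclear_enunciation	motor	bradykinesia	FALSE
slurring	unclear_enunciation	motor	bradykinesia	FALSE
speech disorder	speech_disorder	motor	bradykinesia	FALSE
dysarthria	speech_disorder	motor	bradykinesia	FALSE
falling	falling	motor	postural_instability	FALSE
falls	falling	motor	postural_instability	FALSE
postural instability	gait_postural_instability	motor	postural_instability	FALSE
gait instability	gait_postural_instability	motor	postural_instability	FALSE
unsteady	gait_postural_instability	motor	postural_instability	FALSE
pain	pain	non_motor	sleep_sensory	FALSE
ache	pain	non_motor	sleep_sensory	FALSE
aching	pain	non_motor	sleep_sensory	FALSE
frequent urination	frequent_urination	non_motor	sleep_sensory	FALSE
polyuria	frequent_urination	non_motor	sleep_sensory	FALSE
insomnia	insomnia	non_motor	sleep_sensory	TRUE
sleepless	insomnia	non_motor	sleep_sensory	TRUE
sleeplessness	insomnia	non_motor	sleep_sensory	TRUE
rbd	rbd	non_motor	sleep_sensory	TRUE
dream enactment	rbd	non_motor	sleep_sensory	TRUE
sleep	poor_sleep_quality	non_motor	sleep_sensory	TRUE
poor sleep	poor_sleep_quality	non_motor	sleep_sensory	TRUE
poor sleep quality	poor_sleep_quality	non_motor	sleep_sensory	TRUE
fragmented sleep	fragmented_sleep	non_motor	sleep_sensory	TRUE
broken sleep	fragmented_sleep	non_motor	sleep_sensory	TRUE
nocturia	frequent_nocturia	non_motor	sleep_sensory	TRUE
frequent nocturia	frequent_nocturia	non_motor	sleep_sensory	TRUE
daytime sleepiness	excessive_daytime_sleepiness	non_motor	sleep_sensory	TRUE
drowsiness	excessive_daytime_sleepiness	non_motor	sleep_sensory	TRUE
somnolence	excessive_daytime_sleepiness	non_motor	sleep_sensory	TRUE
numbness	numbness	non_motor	sleep_sensory	FALSE
numb	numbness	non_motor	sleep_sensory	FALSE
tingling	numbness	non_motor	sleep_sensory	FALSE
spasm	spasm	non_motor	sleep_sensory	FALSE
spasms	spasm	non_motor	sleep_sensory	FALSE
cramp	spasm	non_motor	sleep_sensory	FALSE
cramps	spasm	non_motor	sleep_sensory	FALSE
olfactory disorder	olfactory_disorder	non_motor	sleep_sensory	FALSE
smell loss	olfactory_disorder	non_motor	sleep_sensory	FALSE
anosmia	olfactory_disorder	non_motor	sleep_sensory	FALSE
restless legs	restless_legs_syndrome	non_motor	sleep_sensory	FALSE
restless legs syndrome	restless_legs_syndrome	non_motor	sleep_sensory	FALSE
difficulty breathing	difficulty_breathing	non_motor	sleep_sensory	FALSE
breathless	difficulty_breathing	non_motor	sleep_sensory	FALSE
dyspnea	difficulty_breathing	non_motor	sleep_sensory	FALSE
depression	depression	non_motor	cognitive_psychiatric	FALSE
depressed	depression	non_motor	cognitive_psychiatric	FALSE
hallucination	hallucinations	non_motor	cognitive_psychiatric	FALSE
hallucinations	hallucinations	non_motor	cognitive_psychiatric	FALSE
seeing things	hallucinations	non_motor	cognitive_psychiatric	FALSE
dementia	dementia	non_motor	cognitive_psychiatric	FALSE
forgetfulness	dementia	non_motor	cognitive_psychiatric	FALSE
memory loss	dementia	non_motor	cognitive_psychiatric	FALSE
anxiety	anxiety	non_motor	cognitive_psychiatric	FALSE
slow reaction	slow_reaction	non_motor	cognitive_psychiatric	FALSE
slow thinking	slow_reaction	non_motor	cognitive_psychiatric	FALSE
agitation	other_psychiatric	non_motor	cognitive_psychiatric	FALSE
mood swings	other_psychiatric	non_motor	cognitive_psychiatric	FALSE
apathy	apathy	non_motor	cognitive_psychiatric	FALSE
apathetic	apathy	non_motor	cognitive_psychiatric	FALSE
constipation	constipation	non_motor	autonomic	FALSE
constipated	constipation	non_motor	autonomic	FALSE
bloating	gastrointestinal_dysfunction	non_motor	autonomic	FALSE
nausea	gastrointestinal_dysfunction	non_motor	autonomic	FALSE
indigestion	gastrointestinal_dysfunction	non_motor	autonomic	FALSE
drooling	drooling	non_motor	autonomic	FALSE
drool	drooling	non_motor	autonomic	FALSE
salivation	drooling	non_motor	autonomic	FALSE
dyskinesia	dyskinesia	motor_complication	dyskinesia	FALSE
dyskinesias	dyskinesia	motor_complication	dyskinesia	FALSE
involuntary movements	dyskinesia	motor_complication	dyskinesia	FALSE
motor fluctuation	motor_fluctuation	motor_complication	motor_fluctuation	FALSE
wearing off	motor_fluctuation	motor_complication	motor_fluctuation	FALSE
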