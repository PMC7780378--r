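term	grade	label
doubt	1	suspicion
doubtful	1	suspicion
suspicious	1	suspicion
skeptical	1	suspicion
unsure	1	suspicion
worried	2	anxiety
nervous	2	anxiety
anxious	2	anxiety
uneasy	2	anxiety
apprehensive	2	anxiety
afraid	3	fear
scared	3	fear
fearful	3	fear
terrified	3	fear
dread	3	fear
suffering	4	agony
agonizing	4	agony
unbearable	4	agony
tormented	4	agony
misery	4	agony
angry	5	anger
furious	5	anger
resentful	5	anger
frustrated	5	anger
outraged	5	anger
sad	6	sorrow
sorrow	6	sorrow
grief	6	sorrow
hopeless	6	sorrow
despairing	6	sorrow
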