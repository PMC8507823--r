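word	emotion
angry	anger
anger	anger
mad	anger
furious	anger
rage	anger
raging	anger
hate	anger
hated	anger
hatred	anger
annoyed	anger
annoying	anger
irritated	anger
irritating	anger
frustrated	anger
frustrating	anger
frustration	anger
outraged	anger
outrage	anger
resent	anger
resentful	anger
hostile	anger
bitter	anger
fuming	anger
livid	anger
pissed	anger
grudge	anger
insult	anger
insulted	anger
offended	anger
disrespect	anger
disrespected	anger
jealous	anger
envy	anger
revenge	anger
aggressive	anger
temper	anger
tantrum	anger
scream	anger
screaming	anger
yelling	anger
argue	anger
arguing	anger
argument	anger
fight	anger
fighting	anger
violence	anger
violent	anger
cruel	anger
unfair	anger
complains	anger
complain	anger
fear	fear
afraid	fear
scared	fear
scary	fear
terrified	fear
terrifying	fear
frightened	fear
frightening	fear
anxious	fear
anxiety	fear
panic	fear
panicking	fear
nervous	fear
worried	fear
worry	fear
worrying	fear
dread	fear
horror	fear
horrified	fear
alarmed	fear
alarming	fear
threat	fear
threatened	fear
danger	fear
dangerous	fear
unsafe	fear
insecure	fear
paranoid	fear
phobia	fear
timid	fear
tense	fear
uneasy	fear
apprehensive	fear
shaking	fear
trembling	fear
nightmare	fear
nightmares	fear
overwhelmed	fear
stress	fear
stressed	fear
stressful	fear
risk	fear
risky	fear
helpless	fear
vulnerable	fear
seizure	fear
happy	happiness
happiness	happiness
joy	happiness
joyful	happiness
glad	happiness
cheerful	happiness
delighted	happiness
delightful	happiness
excited	happiness
exciting	happiness
love	happiness
loved	happiness
loving	happiness
wonderful	happiness
amazing	happiness
awesome	happiness
fantastic	happiness
fun	happiness
funny	happiness
laugh	happiness
laughing	happiness
laughter	happiness
smile	happiness
smiling	happiness
proud	happiness
pride	happiness
grateful	happiness
thankful	happiness
thanks	happiness
blessed	happiness
hopeful	happiness
hope	happiness
optimistic	happiness
pleasant	happiness
pleased	happiness
enjoy	happiness
enjoyed	happiness
enjoying	happiness
celebrate	happiness
celebration	happiness
satisfied	happiness
relieved	happiness
relief	happiness
thrilled	happiness
sweet	happiness
sad	sadness
sadness	sadness
unhappy	sadness
depressed	sadness
depression	sadness
depressing	sadness
miserable	sadness
misery	sadness
grief	sadness
grieving	sadness
mourning	sadness
heartbroken	sadness
heartbreak	sadness
crying	sadness
cried	sadness
cry	sadness
tears	sadness
tearful	sadness
lonely	sadness
loneliness	sadness
alone	sadness
hopeless	sadness
despair	sadness
gloomy	sadness
gloom	sadness
sorrow	sadness
sorrowful	sadness
hurt	sadness
hurting	sadness
pain	sadness
painful	sadness
suffering	sadness
suffer	sadness
worthless	sadness
regret	sadness
regretful	sadness
disappointed	sadness
disappointing	sadness
ashamed	sadness
shame	sadness
guilty	sadness
guilt	sadness
suicidal	sadness
broken	sadness
vent	sadness
overdosing	sadness
breakdown	sadness
surprise	surprise
surprised	surprise
surprising	surprise
shocked	surprise
shocking	surprise
shock	surprise
astonished	surprise
astonishing	surprise
amazed	surprise
astounded	surprise
stunned	surprise
startled	surprise
unexpected	surprise
unbelievable	surprise
incredible	surprise
sudden	surprise
suddenly	surprise
wow	surprise
whoa	surprise
speechless	surprise
bewildered	surprise
baffled	surprise
confused	surprise
confusing	surprise
curious	surprise
strange	surprise
weird	surprise
odd	surprise
bizarre	surprise
mysterious	surprise
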