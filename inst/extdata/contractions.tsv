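form	expansion
i'm	i am
i've	i have
i'll	i will
i'd	i would
you're	you are
you've	you have
you'll	you will
you'd	you would
he's	he is
she's	she is
it's	it is
we're	we are
we've	we have
we'll	we will
they're	they are
they've	they have
they'll	they will
isn't	is not
aren't	are not
wasn't	was not
weren't	were not
hasn't	has not
haven't	have not
hadn't	had not
doesn't	does not
don't	do not
didn't	did not
won't	will not
wouldn't	would not
can't	cannot
couldn't	could not
shouldn't	should not
mustn't	must not
mightn't	might not
needn't	need not
let's	let us
that's	that is
there's	there is
here's	here is
what's	what is
who's	who is
where's	where is
how's	how is
y'all	you all
o'clock	of the clock
ma'am	madam
dont	do not
cant	cannot
wont	will not
im	i am
ive	i have
youre	you are
theyre	they are
isnt	is not
doesnt	does not
didnt	did not
wouldnt	would not
couldnt	could not
shouldnt	should not
thats	that is
whats	what is
theres	there is
u	you
ur	your
r	are
thx	thanks
pls	please
plz	please
omg	oh my god
idk	i do not know
tbh	to be honest
btw	by the way
rn	right now
irl	in real life
imo	in my opinion
smh	shaking my head
gonna	going to
wanna	want to
gotta	got to
lemme	let me
gimme	give me
tho	though
thru	through
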