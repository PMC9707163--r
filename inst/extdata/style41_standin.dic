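%
1	i
2	we
3	you
4	shehe
5	they
6	ipron
7	ppron
8	pronoun
9	article
10	prep
11	auxverb
12	modal
13	adverb
14	conj
15	conjsub
16	negate
17	quant
18	number
19	interrog
20	compare
21	certain
22	tentat
23	discrep
24	assent
25	nonflu
26	filler
27	netspeak
28	hedge
29	intens
30	demonstr
31	possess
32	reflex
33	relpron
34	exist
35	beverb
36	haveverb
37	doverb
38	focusfuture
39	focuspast
40	causation
%
a	9
about	10
above	10
absolutely	21	24	29
across	10
actually	13
afaik	27
affect	40
affects	40
after	10	15
again	13
against	10
ago	39
agree	24
agreed	24
agrees	24
ah	25
ahead	38
ahh	25
ain't	16	35
alike	20
all	17
almost	13	22
along	10
already	13
alright	24
also	13
although	15
always	13	21
am	11	35
among	10
an	9
and	14
another	6	8
any	17
anybody	6	8
anyhow	25
anyone	6	8
anything	6	8
anyway	26
anyways	26
apparently	22
approximately	28
are	11	35
aren't	16	35
arguably	22	28
around	10
as	15	20
at	10
basically	26
be	11	35
because	15	40
been	11	35
before	10	15	39
behind	10
being	11	35
below	10
beneath	10
beside	10
besides	10
best	20
better	20
between	10
beyond	10
bigger	20
billion	18
blah	26
both	17
brb	27
broadly	28
btw	27
bunch	17
but	14
by	10
can	11	12
can't	12	16
cannot	12	16
cause	40
caused	40
causes	40
causing	40
certain	21
certainly	21
clearly	21
completely	21	29
consequently	40
cool	24
cos	40
could	11	12	23
coulda	23
couldn't	12	16
cuz	40
deeply	29
definitely	21	24
depending	22
depends	22
despite	10
did	11	37	39
didn't	16	37
different	20
do	11	37
does	11	37
doesn't	16	37
doing	11	37
don't	16	37
done	37	39
double	18
down	10
dozen	18
due	40
dunno	27
during	10
each	17
earlier	39
effect	40
effects	40
eh	25
eight	18
either	14
eleven	18
enough	17
entire	17
equal	20
er	25
especially	13
etc	26
etcetera	26
eventually	38
every	17
everybody	6	8
everyone	6	8
everything	6	8
exactly	21	24
except	10
expect	23
expected	23
expecting	23
expects	23
extremely	29
fairly	13	28
faster	20
few	17
fewer	17
fifth	18
fifty	18
finally	13
fine	24
first	18
five	18
for	10	14
former	39
formerly	39
forty	18
four	18
fourth	18
from	10
ftw	27
future	38
fyi	27
generally	28
gimme	27
gonna	27	38
gotta	27
greater	20
guaranteed	21
guess	22
guessing	22
had	11	36	39
hadn't	16	36
half	17
has	11	36
hasn't	16	36
have	11	36
haven't	16	36
having	11	36
he	4	7	8
he's	4	7	8
hence	40
her	4	7	8	31
here	13	34
here's	34
hers	4	7	8	31
herself	4	7	8	32
higher	20
highly	29
him	4	7	8
himself	4	7	8	32
his	4	7	8	31
hm	25
hmm	25
honestly	26
hope	23
hoped	23
hopefully	23
hopes	23
hoping	23
how	19
hugely	29
huh	25
hundred	18
i	1	7	8
i'd	1	7	8
i'll	1	7	8
i'm	1	7	8
i've	1	7	8
ideally	23
idk	27
if	15
iirc	27
imho	27
imo	27
in	10
incredibly	29
indeed	24
inevitably	21
insanely	29
inside	10
instead	13	23
into	10
irl	27
is	11	35
isn't	16	35
it	6	8
it's	6	8
its	6	8	31
itself	6	8	32
just	13
kind	22
kinda	22	27
largely	28
larger	20
lately	39
later	38
leads	40
least	17
led	40
lemme	27
less	17
like	20
likely	22
literally	26
lmao	27
loads	17
lol	27
lot	17
lots	17
lower	20
many	17
massively	29
may	11	12	22
maybe	13	22
me	1	7	8
meh	25
might	11	12	22
million	18
mine	1	7	8	31
more	17
most	17
mostly	13	28
much	17
must	11	12
my	1	7	8	31
myself	1	7	8	32
nah	16
near	10
nearly	13	22
need	23
needed	23
needing	23
needs	23
neither	14	16
never	13	16	21
next	38
nine	18
no	16
nobody	6	8	16
none	16
nope	16
nor	14	16
not	16
nothing	6	8	16
now	13
nowhere	16
nvm	27
obvious	21
obviously	21
of	10
off	10
often	13
oh	25
ok	24
okay	24
omg	27
on	10
once	15	18	39
one	6	8	18
ones	6	8
oneself	32
onto	10
or	14
other	6	8
others	6	8
ought	11	12	23
our	2	7	8	31
ours	2	7	8	31
ourselves	2	7	8	32
outside	10
over	10
partially	28
partly	28
past	39
perhaps	13	22
planning	38
plans	38
plenty	17
pls	27
plus	14
plz	27
possibly	22
prefer	23
preferred	23
prefers	23
presumably	22
pretty	13
previously	39
probably	22
quickly	13
quite	13	28
rarely	13
rather	13	23	28
really	13	29
reason	40
reasons	40
recently	39
relatively	28
result	40
resulted	40
results	40
ridiculously	29
right	24
rofl	27
roughly	22	28
same	20
second	18
seriously	26	29
seven	18
several	17
shall	11	12	38
she	4	7	8
she's	4	7	8
should	11	12	23
shoulda	23
shouldn't	12	16
similar	20
since	15	40
single	18
six	18
slightly	28
slower	20
slowly	13
smaller	20
smh	27
so	13	14	29
some	17
somebody	6	8
someday	38
someone	6	8
something	6	8
sometimes	13
somewhat	22	28
soon	13	38
sort	22
sorta	22	27
still	13
stronger	20
strongly	29
stuff	6	8	26
super	29
supposedly	22
sure	21	24
surely	21
tbh	27
ten	18
than	20
that	6	8	30	33
that's	6	8
the	9
their	5	7	8	31
theirs	5	7	8	31
them	5	7	8
themselves	5	7	8	32
then	13
there	13	34
there's	34
thereby	40
therefore	40
these	6	8	30
they	5	7	8
they'd	5	7	8
they'll	5	7	8
they're	5	7	8
they've	5	7	8
thing	6	8
things	6	8	26
third	18
thirty	18
this	6	8	30
those	6	8	30
though	15
thousand	18
three	18
through	10
thus	40
thx	27
tldr	27
to	10
together	13
tomorrow	38
tons	17
too	13
totally	21	29
toward	10
towards	10
triple	18
truly	21
twelve	18
twenty	18
twice	18
two	18
typically	28
u	3	7	8
ugh	25
uh	25
uhh	25
um	25
umm	25
undeniably	21
under	10
undoubtedly	21
unless	15
unlike	20
unlikely	22
unsure	22
until	10	15
up	10
upcoming	38
upon	10
us	2	7	8
used	39
usually	13
utterly	29
versus	20
very	13	29
via	10
virtually	28
vs	20
wanna	27
want	23
wanted	23
wanting	23
wants	23
was	11	35	39
wasn't	16	35
we	2	7	8
we'd	2	7	8
we'll	2	7	8
we're	2	7	8
we've	2	7	8
weaker	20
well	13
welp	25
were	11	35	39
weren't	16	35
what	8	19
what's	19
whatever	26	33
when	15	19	33
whenever	15
where	15	19	33
where's	19
whereas	15
wherever	15
whether	14	19
which	8	19	33
whichever	33
while	15
whilst	15
who	8	19	33
who's	19
whoever	33
whole	17
whom	8	19	33
whose	8	19	33
why	19
will	11	12	38
wish	23
wished	23
wishes	23
wishing	23
with	10
within	10
without	10	16
won't	12	16
worse	20
worst	20
would	11	12	23
woulda	23
wouldn't	12	16
wtf	27
ya	3	7	8
yada	26
yeah	24
yep	24
yes	24
yesterday	39
yet	13	14
you	3	7	8
you'd	3	7	8
you'll	3	7	8
you're	3	7	8
you've	3	7	8
your	3	7	8	31
yours	3	7	8	31
yourself	3	7	8	32
yourselves	3	7	8	32
yup	24
zero	18
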