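# Function-word stoplist: articles, prepositions, pronouns, auxiliaries,
# conjunctions, interjections and fillers. One word per line; '#' comments.
# articles & determiners
a
an
the
this
that
these
those
each
every
either
neither
some
any
no
another
such
what
which
whose
# pronouns
i
me
my
mine
myself
we
us
our
ours
ourselves
you
your
yours
yourself
yourselves
he
him
his
himself
she
her
hers
herself
it
its
itself
they
them
their
theirs
themselves
who
whom
somebody
someone
something
anybody
anyone
anything
everybody
everyone
everything
nobody
nothing
one
ones
# auxiliaries & copulas
am
is
are
was
were
be
been
being
have
has
had
having
do
does
did
doing
will
would
shall
should
can
could
may
might
must
ought
won't
wouldn't
can't
cannot
couldn't
shouldn't
mustn't
isn't
aren't
wasn't
weren't
hasn't
haven't
hadn't
don't
doesn't
didn't
i'm
i've
i'll
i'd
you're
you've
you'll
he's
she's
it's
we're
we've
they're
they've
that's
there's
here's
what's
let's
# prepositions & particles
of
in
on
at
by
for
with
about
against
between
into
through
during
before
after
above
below
to
from
up
down
out
off
over
under
again
further
then
once
here
there
where
when
why
how
as
than
too
very
not
only
own
same
so
just
also
# conjunctions
and
but
or
nor
if
because
until
while
whether
although
though
unless
since
# interjections & fillers
um
uh
er
erm
ah
oh
eh
hm
hmm
mm
mmm
yeah
yes
okay
ok
gonna
wanna
gotta
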